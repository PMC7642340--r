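// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cstring>
using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uvec;

// Small 1-D convolutional network for raw-signal classification:
// a stack of (convolution -> ReLU -> average pooling -> batch
// normalization) blocks, two fully connected layers with dropout, and a
// softmax output. Single-threaded, trained with Adam; all randomness
// (init, shuffling, dropout) comes from R's RNG so results are
// reproducible under set.seed().

static const double BN_EPS = 1e-5;
static const double BN_MOMENTUM = 0.1;

struct Adam {
  mat mW, vW;
  vec mb, vb;
  void init(const mat& W, const vec& b) {
    mW.zeros(W.n_rows, W.n_cols); vW.zeros(W.n_rows, W.n_cols);
    mb.zeros(b.n_elem); vb.zeros(b.n_elem);
  }
};

static void adam_step(mat& W, vec& b, const mat& dW, const vec& db,
                      Adam& st, double lr, int t) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  st.mW = b1 * st.mW + (1 - b1) * dW;
  st.vW = b2 * st.vW + (1 - b2) * (dW % dW);
  st.mb = b1 * st.mb + (1 - b1) * db;
  st.vb = b2 * st.vb + (1 - b2) * (db % db);
  double c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
  W -= lr * (st.mW / c1) / (arma::sqrt(st.vW / c2) + eps);
  b -= lr * (st.mb / c1) / (arma::sqrt(st.vb / c2) + eps);
}

struct ConvBlock {
  int cin, cout, k, pool, lin, lconv, lout;
  mat W;            // (cout, k*cin)
  vec b, gamma, beta, rmean, rvar;
  Adam aW, agb;     // agb: Adam over gamma (as 1-col mat) and beta
  Adam agamma;
  // caches for backward
  mat M;            // im2col matrix (k*cin, lconv*B)
  arma::umat relu_mask;
  mat xhat;
  vec istd;
};

struct Dense {
  mat W; vec b;
  Adam ad;
  mat in, relu_in;  // caches
  arma::umat drop_mask;
};

static double runif01() { return unif_rand(); }

static void he_init(mat& W, double fan_in) {
  double sd = std::sqrt(2.0 / fan_in);
  for (arma::uword i = 0; i < W.n_elem; ++i) W[i] = norm_rand() * sd;
}

// im2col: A is (C, L*B) with column index b*L + l
static void im2col(const mat& A, int C, int L, int B, int k, mat& M) {
  int Lc = L - k + 1;
  M.set_size(k * C, (arma::uword)Lc * B);
  for (int bb = 0; bb < B; ++bb)
    for (int l = 0; l < Lc; ++l) {
      double* dst = M.colptr((arma::uword)bb * Lc + l);
      for (int kk = 0; kk < k; ++kk)
        std::memcpy(dst + kk * C, A.colptr((arma::uword)bb * L + l + kk),
                    C * sizeof(double));
    }
}

static void col2im_add(mat& dA, int C, int L, int B, int k, const mat& dM) {
  int Lc = L - k + 1;
  for (int bb = 0; bb < B; ++bb)
    for (int l = 0; l < Lc; ++l) {
      const double* src = dM.colptr((arma::uword)bb * Lc + l);
      for (int kk = 0; kk < k; ++kk) {
        double* dst = dA.colptr((arma::uword)bb * L + l + kk);
        for (int c = 0; c < C; ++c) dst[c] += src[kk * C + c];
      }
    }
}

// forward through one conv block; A in (cin, lin*B) -> out (cout, lout*B)
static mat conv_forward(ConvBlock& cb, const mat& A, int B, bool train) {
  im2col(A, cb.cin, cb.lin, B, cb.k, cb.M);
  mat Z = cb.W * cb.M;
  Z.each_col() += cb.b;
  cb.relu_mask = (Z > 0);
  Z = Z % cb.relu_mask;
  // average pooling (non-overlapping)
  mat P(cb.cout, (arma::uword)cb.lout * B);
  for (int bb = 0; bb < B; ++bb)
    for (int l = 0; l < cb.lout; ++l) {
      vec acc = Z.col((arma::uword)bb * cb.lconv + l * cb.pool);
      for (int p = 1; p < cb.pool; ++p)
        acc += Z.col((arma::uword)bb * cb.lconv + l * cb.pool + p);
      P.col((arma::uword)bb * cb.lout + l) = acc / cb.pool;
    }
  // batch normalization per channel
  if (train) {
    vec mu = arma::mean(P, 1);
    mat cent = P.each_col() - mu;
    vec var = arma::mean(cent % cent, 1);
    cb.istd = 1.0 / arma::sqrt(var + BN_EPS);
    cb.xhat = cent.each_col() % cb.istd;
    cb.rmean = (1 - BN_MOMENTUM) * cb.rmean + BN_MOMENTUM * mu;
    cb.rvar = (1 - BN_MOMENTUM) * cb.rvar + BN_MOMENTUM * var;
    mat out = cb.xhat.each_col() % cb.gamma;
    out.each_col() += cb.beta;
    return out;
  } else {
    vec istd = 1.0 / arma::sqrt(cb.rvar + BN_EPS);
    mat out = (P.each_col() - cb.rmean).each_col() % (cb.gamma % istd);
    out.each_col() += cb.beta;
    return out;
  }
}

// backward through one conv block; returns gradient w.r.t. the block input
static mat conv_backward(ConvBlock& cb, const mat& dOut, int B,
                         double lr, int step) {
  const double N = (double)dOut.n_cols;
  vec dgamma = arma::sum(dOut % cb.xhat, 1);
  vec dbeta = arma::sum(dOut, 1);
  mat dxhat = dOut.each_col() % cb.gamma;
  vec sum_dxhat = arma::sum(dxhat, 1);
  vec sum_dxhat_xhat = arma::sum(dxhat % cb.xhat, 1);
  mat dP = dxhat;
  dP.each_col() -= sum_dxhat / N;
  dP -= cb.xhat.each_col() % (sum_dxhat_xhat / N);
  dP.each_col() %= cb.istd;
  // update gamma/beta with Adam (reuse mat-based optimizer on 1-col mats)
  {
    mat g(cb.gamma.n_elem, 1), dg(dgamma.n_elem, 1);
    g.col(0) = cb.gamma; dg.col(0) = dgamma;
    adam_step(g, cb.beta, dg, dbeta, cb.agamma, lr, step);
    cb.gamma = g.col(0);
  }
  // un-pool
  mat dZ(cb.cout, (arma::uword)cb.lconv * B, arma::fill::zeros);
  for (int bb = 0; bb < B; ++bb)
    for (int l = 0; l < cb.lout; ++l) {
      vec g = dP.col((arma::uword)bb * cb.lout + l) / cb.pool;
      for (int p = 0; p < cb.pool; ++p)
        dZ.col((arma::uword)bb * cb.lconv + l * cb.pool + p) = g;
    }
  dZ = dZ % cb.relu_mask;
  mat dW = dZ * cb.M.t();
  vec db = arma::sum(dZ, 1);
  mat dM = cb.W.t() * dZ;
  adam_step(cb.W, cb.b, dW, db, cb.aW, lr, step);
  mat dA(cb.cin, (arma::uword)cb.lin * B, arma::fill::zeros);
  col2im_add(dA, cb.cin, cb.lin, B, cb.k, dM);
  return dA;
}

struct Net {
  std::vector<ConvBlock> blocks;
  Dense fc1, fc2, out;
  int input_length, n_classes, flat_dim;
};

static void build_net(Net& net, int input_length, int n_classes,
                      const IntegerMatrix& blocks, const IntegerVector& fc_sizes) {
  int L = input_length, C = 1;
  net.input_length = input_length;
  net.n_classes = n_classes;
  for (int i = 0; i < blocks.nrow(); ++i) {
    ConvBlock cb;
    cb.cin = C;
    cb.cout = blocks(i, 0);
    cb.k = blocks(i, 1);
    cb.pool = blocks(i, 2);
    cb.lin = L;
    cb.lconv = L - cb.k + 1;
    if (cb.lconv < cb.pool)
      stop("signal too short for the configured conv blocks");
    cb.lout = cb.lconv / cb.pool;
    cb.W.set_size(cb.cout, cb.k * cb.cin);
    he_init(cb.W, cb.k * cb.cin);
    cb.b.zeros(cb.cout);
    cb.gamma.ones(cb.cout);
    cb.beta.zeros(cb.cout);
    cb.rmean.zeros(cb.cout);
    cb.rvar.ones(cb.cout);
    cb.aW.init(cb.W, cb.b);
    {
      mat g(cb.cout, 1, arma::fill::zeros);
      cb.agamma.init(g, cb.beta);
    }
    net.blocks.push_back(cb);
    C = cb.cout;
    L = cb.lout;
  }
  net.flat_dim = C * L;
  net.fc1.W.set_size(fc_sizes[0], net.flat_dim);
  he_init(net.fc1.W, net.flat_dim);
  net.fc1.b.zeros(fc_sizes[0]);
  net.fc1.ad.init(net.fc1.W, net.fc1.b);
  net.fc2.W.set_size(fc_sizes[1], fc_sizes[0]);
  he_init(net.fc2.W, fc_sizes[0]);
  net.fc2.b.zeros(fc_sizes[1]);
  net.fc2.ad.init(net.fc2.W, net.fc2.b);
  net.out.W.set_size(n_classes, fc_sizes[1]);
  he_init(net.out.W, fc_sizes[1]);
  net.out.b.zeros(n_classes);
  net.out.ad.init(net.out.W, net.out.b);
}

static mat flatten_batch(const mat& A, int C, int L, int B) {
  mat F(C * L, B);
  for (int bb = 0; bb < B; ++bb) {
    const mat sub = A.cols((arma::uword)bb * L, (arma::uword)(bb + 1) * L - 1);
    F.col(bb) = arma::vectorise(sub);
  }
  return F;
}

static arma::umat dropout_mask(arma::uword r, arma::uword c, double p) {
  arma::umat m(r, c);
  for (arma::uword i = 0; i < m.n_elem; ++i) m[i] = runif01() >= p;
  return m;
}

// forward pass; probabilities (n_classes x B)
static mat net_forward(Net& net, const mat& Xb, bool train, double dropout) {
  int B = Xb.n_cols;
  // input as (1, L*B)
  mat A(1, (arma::uword)net.input_length * B);
  for (int bb = 0; bb < B; ++bb)
    for (int l = 0; l < net.input_length; ++l)
      A(0, (arma::uword)bb * net.input_length + l) = Xb(l, bb);
  for (size_t i = 0; i < net.blocks.size(); ++i)
    A = conv_forward(net.blocks[i], A, B, train);
  ConvBlock& last = net.blocks.back();
  mat F = flatten_batch(A, last.cout, last.lout, B);
  net.fc1.in = F;
  mat H1 = net.fc1.W * F;
  H1.each_col() += net.fc1.b;
  net.fc1.relu_in = H1;
  H1 = arma::clamp(H1, 0.0, arma::datum::inf);
  if (train && dropout > 0) {
    net.fc1.drop_mask = dropout_mask(H1.n_rows, H1.n_cols, dropout);
    H1 = (H1 % net.fc1.drop_mask) / (1 - dropout);
  }
  net.fc2.in = H1;
  mat H2 = net.fc2.W * H1;
  H2.each_col() += net.fc2.b;
  net.fc2.relu_in = H2;
  H2 = arma::clamp(H2, 0.0, arma::datum::inf);
  if (train && dropout > 0) {
    net.fc2.drop_mask = dropout_mask(H2.n_rows, H2.n_cols, dropout);
    H2 = (H2 % net.fc2.drop_mask) / (1 - dropout);
  }
  net.out.in = H2;
  mat O = net.out.W * H2;
  O.each_col() += net.out.b;
  // softmax
  arma::rowvec mx = arma::max(O, 0);
  O.each_row() -= mx;
  O = arma::exp(O);
  arma::rowvec s = arma::sum(O, 0);
  O.each_row() /= s;
  return O;
}

static void net_backward(Net& net, const mat& P, const uvec& yb,
                         double dropout, double lr, int step) {
  int B = P.n_cols;
  mat dO = P;
  for (int bb = 0; bb < B; ++bb) dO(yb[bb], bb) -= 1.0;
  dO /= B;
  mat dW = dO * net.out.in.t();
  vec db = arma::sum(dO, 1);
  mat dH2 = net.out.W.t() * dO;
  adam_step(net.out.W, net.out.b, dW, db, net.out.ad, lr, step);
  if (dropout > 0) dH2 = (dH2 % net.fc2.drop_mask) / (1 - dropout);
  dH2 = dH2 % (net.fc2.relu_in > 0);
  dW = dH2 * net.fc2.in.t();
  db = arma::sum(dH2, 1);
  mat dH1 = net.fc2.W.t() * dH2;
  adam_step(net.fc2.W, net.fc2.b, dW, db, net.fc2.ad, lr, step);
  if (dropout > 0) dH1 = (dH1 % net.fc1.drop_mask) / (1 - dropout);
  dH1 = dH1 % (net.fc1.relu_in > 0);
  dW = dH1 * net.fc1.in.t();
  db = arma::sum(dH1, 1);
  mat dF = net.fc1.W.t() * dH1;
  adam_step(net.fc1.W, net.fc1.b, dW, db, net.fc1.ad, lr, step);
  // unflatten
  ConvBlock& last = net.blocks.back();
  mat dA(last.cout, (arma::uword)last.lout * B);
  for (int bb = 0; bb < B; ++bb)
    dA.cols((arma::uword)bb * last.lout, (arma::uword)(bb + 1) * last.lout - 1) =
      arma::reshape(dF.col(bb), last.cout, last.lout);
  for (int i = (int)net.blocks.size() - 1; i >= 0; --i)
    dA = conv_backward(net.blocks[i], dA, B, lr, step);
}

static List net_to_list(const Net& net) {
  List conv(net.blocks.size());
  for (size_t i = 0; i < net.blocks.size(); ++i) {
    const ConvBlock& cb = net.blocks[i];
    conv[i] = List::create(
      _["W"] = cb.W, _["b"] = cb.b, _["gamma"] = cb.gamma, _["beta"] = cb.beta,
      _["rmean"] = cb.rmean, _["rvar"] = cb.rvar,
      _["cin"] = cb.cin, _["cout"] = cb.cout, _["k"] = cb.k, _["pool"] = cb.pool);
  }
  return List::create(
    _["conv"] = conv,
    _["fc1_W"] = net.fc1.W, _["fc1_b"] = net.fc1.b,
    _["fc2_W"] = net.fc2.W, _["fc2_b"] = net.fc2.b,
    _["out_W"] = net.out.W, _["out_b"] = net.out.b,
    _["input_length"] = net.input_length,
    _["n_classes"] = net.n_classes);
}

static void net_from_list(Net& net, const List& params) {
  List conv = params["conv"];
  net.input_length = as<int>(params["input_length"]);
  net.n_classes = as<int>(params["n_classes"]);
  int L = net.input_length;
  for (int i = 0; i < conv.size(); ++i) {
    List li = conv[i];
    ConvBlock cb;
    cb.W = as<mat>(li["W"]);
    cb.b = as<vec>(li["b"]);
    cb.gamma = as<vec>(li["gamma"]);
    cb.beta = as<vec>(li["beta"]);
    cb.rmean = as<vec>(li["rmean"]);
    cb.rvar = as<vec>(li["rvar"]);
    cb.cin = as<int>(li["cin"]);
    cb.cout = as<int>(li["cout"]);
    cb.k = as<int>(li["k"]);
    cb.pool = as<int>(li["pool"]);
    cb.lin = L;
    cb.lconv = L - cb.k + 1;
    cb.lout = cb.lconv / cb.pool;
    L = cb.lout;
    net.blocks.push_back(cb);
  }
  net.fc1.W = as<mat>(params["fc1_W"]); net.fc1.b = as<vec>(params["fc1_b"]);
  net.fc2.W = as<mat>(params["fc2_W"]); net.fc2.b = as<vec>(params["fc2_b"]);
  net.out.W = as<mat>(params["out_W"]); net.out.b = as<vec>(params["out_b"]);
  ConvBlock& last = net.blocks.back();
  net.flat_dim = last.cout * last.lout;
}

static double batch_accuracy(const mat& P, const uvec& y) {
  int correct = 0;
  for (arma::uword b = 0; b < P.n_cols; ++b) {
    arma::uword pred;
    P.col(b).max(pred);
    if (pred == y[b]) ++correct;
  }
  return (double)correct / P.n_cols;
}

// [[Rcpp::export]]
List cpp_cnn_train(const arma::mat& X, const IntegerVector& y, int n_classes,
                   const IntegerMatrix& blocks, const IntegerVector& fc_sizes,
                   double dropout, int epochs, int batch_size, double lr,
                   const arma::mat& Xval, const IntegerVector& yval,
                   bool verbose) {
  // X: (input_length x n_samples), y 0-based
  const int n = X.n_cols;
  Net net;
  build_net(net, X.n_rows, n_classes, blocks, fc_sizes);
  uvec yy(n);
  for (int i = 0; i < n; ++i) yy[i] = y[i];
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  NumericVector ep_loss(epochs), ep_tacc(epochs), ep_vacc(epochs);
  int step = 0;
  // cosine decay of the learning rate to 10% of its initial value
  const int steps_per_epoch = (n + batch_size - 1) / batch_size;
  const int total_steps = std::max(1, epochs * steps_per_epoch);
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle with R's RNG
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(runif01() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }
    double loss_sum = 0, acc_sum = 0;
    int nb = 0;
    for (int start = 0; start < n; start += batch_size) {
      int B = std::min(batch_size, n - start);
      if (B < 2) continue;  // batch norm needs > 1 sample
      mat Xb(X.n_rows, B);
      uvec yb(B);
      for (int b = 0; b < B; ++b) {
        Xb.col(b) = X.col(order[start + b]);
        yb[b] = yy[order[start + b]];
      }
      mat P = net_forward(net, Xb, true, dropout);
      double loss = 0;
      for (int b = 0; b < B; ++b)
        loss -= std::log(std::max(P(yb[b], b), 1e-12));
      loss /= B;
      loss_sum += loss;
      acc_sum += batch_accuracy(P, yb);
      ++nb;
      ++step;
      double lr_t = 0.1 * lr + 0.45 * lr *
        (1.0 + std::cos(M_PI * (double)step / total_steps));
      net_backward(net, P, yb, dropout, lr_t, step);
    }
    ep_loss[ep] = loss_sum / std::max(nb, 1);
    ep_tacc[ep] = acc_sum / std::max(nb, 1);
    // validation accuracy, eval mode
    if (Xval.n_cols > 0) {
      int nv = Xval.n_cols, correct = 0;
      for (int start = 0; start < nv; start += batch_size) {
        int B = std::min(batch_size, nv - start);
        mat Xb = Xval.cols(start, start + B - 1);
        mat P = net_forward(net, Xb, false, 0.0);
        for (int b = 0; b < B; ++b) {
          arma::uword pred;
          P.col(b).max(pred);
          if ((int)pred == yval[start + b]) ++correct;
        }
      }
      ep_vacc[ep] = (double)correct / nv;
    } else {
      ep_vacc[ep] = NA_REAL;
    }
    if (verbose)
      Rcpp::Rcout << "epoch " << (ep + 1) << " loss " << ep_loss[ep]
                  << " train_acc " << ep_tacc[ep]
                  << " val_acc " << ep_vacc[ep] << "\n";
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["params"] = net_to_list(net),
                      _["train_loss"] = ep_loss,
                      _["train_accuracy"] = ep_tacc,
                      _["val_accuracy"] = ep_vacc);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(const List& params, const arma::mat& X, int batch_size) {
  Net net;
  net_from_list(net, params);
  const int n = X.n_cols;
  mat out(net.n_classes, n);
  for (int start = 0; start < n; start += batch_size) {
    int B = std::min(batch_size, n - start);
    mat Xb = X.cols(start, start + B - 1);
    out.cols(start, start + B - 1) = net_forward(net, Xb, false, 0.0);
  }
  return out.t();  // (n x n_classes)
}
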