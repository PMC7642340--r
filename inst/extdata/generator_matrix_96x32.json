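{
  "n": 96,
  "k": 32,
  "t": 9,
  "required_min_distance": 19,
  "seed": 20201103,
  "verified_weight_floor": 19,
  "search_iters": 100000,
  "rows": ["f650d761388e42a58bdd27e3", "5985c384246ed07a468615ea", "991ff304c267f0afee7b32b1", "559b7a08afc38e3dfe93405e", "70dae3f9e46e128f4fb671ec", "c920ebd4683f291ad5a84c31", "b34cbf4d3b863eb85999442d", "c0510be875cf6e14861a6bd9", "aecb4caa551f29a3d60503bc", "550546e9d18d9e4f52b5c2e4", "c605f510481502e2caae8fdd", "eb6f8dca5dd9d700b1ed7997", "6133bdf6cc15ab62e2ab076b", "84bff70c56b780fc44175c40", "4925d3c82a813f43f828149b", "8a7b9b753a4752efe7c1b15d", "02f6176354aef67a5617bb6b", "f04e7b0e834ab10db5d43d17", "35c1a2d8b4c5e32726d72ce3", "0b58c97585796ed381334de4", "f46bbffbd4941ac39fbc4fda", "c6fd2e0cb0670f7a6518600d", "93758fd094b6b1693a4dc024", "235d644b0cc4b70cc2374afa", "557a8bf05f3a28a3d70fc9d0", "1d54a2c9c65e9d54033eb6c8", "90275761d9237ead9b94849d", "be6807631690d3f10152b704", "a248f258a1359298a346f1e7", "186d0d47595862eaa9d2a4d3", "62e780aacf14b495acd67b48", "642e82bdbb1803f23cb40124"]
}
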