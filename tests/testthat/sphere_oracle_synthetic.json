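{
 "pos": [
  [
   0.0,
   0.0,
   0.069
  ],
  [
   0.05806149795174487,
   0.0,
   0.03728085910490165
  ],
  [
   0.0,
   0.06431069693173862,
   0.025002685058890483
  ],
  [
   -0.02059825728549059,
   0.04500801328251395,
   0.04807276294495442
  ]
 ],
 "ori": [
  [
   0.0,
   0.0,
   1.0
  ],
  [
   0.8414709848078965,
   0.0,
   0.5403023058681398
  ],
  [
   1.0,
   0.0,
   0.0
  ],
  [
   0.0,
   0.0,
   1.0
  ]
 ],
 "dippos": [
  [
   0.0,
   0.045,
   0.015
  ],
  [
   0.02,
   -0.03,
   0.03
  ]
 ],
 "dipori": [
  [
   1.0,
   0.0,
   0.0
  ],
  [
   0.0,
   0.6,
   0.8
  ]
 ],
 "field_per_Am": [
  [
   -1.2956576028955169e-05,
   8.008969416550826e-06
  ],
  [
   -5.375164164433954e-06,
   -2.4518478312529624e-05
  ],
  [
   0.0,
   3.7441982385644224e-06
  ],
  [
   -2.1949123038211837e-05,
   -1.1357625595564969e-07
  ]
 ]
}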