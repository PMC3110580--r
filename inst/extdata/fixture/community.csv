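plot,species,abundance
plot01,sp0001,0.3
plot01,sp0002,0.3
plot01,sp0004,0.4
plot01,sp0006,0.7
plot01,sp0007,0.8
plot01,sp0008,0.7
plot01,sp0010,0.2
plot01,sp0011,0.7
plot01,sp0012,0.3
plot02,sp0002,0.3
plot02,sp0004,0.5
plot02,sp0006,0.6
plot02,sp0007,0.6
plot02,sp0008,0.4
plot02,sp0009,0.1
plot02,sp0010,0.1
plot02,sp0011,0.9
plot02,sp0012,0.5
plot03,sp0001,0.3
plot03,sp0002,0.1
plot03,sp0004,0.7
plot03,sp0006,0.6
plot03,sp0007,0.5
plot03,sp0008,0.2
plot03,sp0011,0.8
plot03,sp0012,0.7
plot04,sp0001,0.7
plot04,sp0002,0.5
plot04,sp0003,0.9
plot04,sp0005,0.7
plot04,sp0006,0.2
plot04,sp0007,0.4
plot04,sp0008,0.4
plot04,sp0009,0.6
plot04,sp0010,0.7
plot04,sp0011,0.1
plot05,sp0001,0.7
plot05,sp0002,0.7
plot05,sp0003,0.7
plot05,sp0005,0.3
plot05,sp0006,0.4
plot05,sp0007,0.1
plot05,sp0008,0.5
plot05,sp0009,0.3
plot05,sp0010,0.4
plot05,sp0011,0.2
plot06,sp0001,0.7
plot06,sp0002,0.7
plot06,sp0003,0.4
plot06,sp0005,0.6
plot06,sp0006,0.1
plot06,sp0007,0.3
plot06,sp0008,0.2
plot06,sp0009,0.2
plot06,sp0010,0.6
plot06,sp0011,0.1
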