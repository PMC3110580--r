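species,height
sp0001,2.0556428054325138
sp0002,1.7271119083204023
sp0003,1.731389995370605
sp0004,1.6654571974512031
sp0005,1.6283161618211381
sp0006,1.3473191641007016
sp0007,1.4531577169528382
sp0008,1.342268141357582
sp0009,1.7163350802768234
sp0010,1.6529169032315012
sp0011,1.2343674024213647
sp0012,1.6457175232633277
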