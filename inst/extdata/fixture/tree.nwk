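(((((sp0011:3.373473156,sp0008:3.373473156):5.213227378,sp0006:8.586700535):24.90535409,sp0005:33.49205462):97.70815795,(((sp0009:1.084797702,sp0010:1.084797702):8.705792044,((sp0002:1.312677189,sp0012:1.312677189):7.942141542,sp0004:9.254818731):0.5357710148):105.677399,(sp0007:17.14165374,sp0003:17.14165374):98.32633504):15.7322238):7.799787423,sp0001:139);
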