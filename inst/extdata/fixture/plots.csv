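plot,habitat,site,env
plot01,habitat1,site1,-0.4019122615409378
plot02,habitat1,site1,-0.49714215926456734
plot03,habitat1,site1,-0.7774255971078171
plot04,habitat2,site2,0.48008550321457366
plot05,habitat2,site2,0.3201772723193995
plot06,habitat2,site2,0.30053877917968885
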