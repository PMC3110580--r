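plant_id,species,plot,sla,leaf_size,srl
pl00001,sp0001,plot01,2.4868260356496745,0.7200952649195739,2.081006629457966
pl00019,sp0001,plot03,2.2853280934478026,0.5446944506379819,1.9405293319501526
pl00027,sp0001,plot04,2.7944763284163363,0.8945150203055896,2.23446346261198
pl00037,sp0001,plot05,NA,0.936670834768211,2.2240519891432116
pl00047,sp0001,plot06,2.6610970908113316,0.905219339699611,2.2556048208541446
pl00002,sp0002,plot01,2.223353805553002,0.32375744589476635,1.6419197936210366
pl00010,sp0002,plot02,2.056991706797733,0.3957383417968615,1.5291292387490303
pl00020,sp0002,plot03,2.0802262405552425,0.19064194895035846,1.4914267489852329
pl00028,sp0002,plot04,2.401966750780794,0.7253741070211546,1.786252014222636
pl00038,sp0002,plot05,2.3332984761258415,0.5513097693590069,1.8050051651713523
pl00048,sp0002,plot06,2.3183454393066825,0.6004159553230651,1.774056119602272
pl00029,sp0003,plot04,2.0809953499332123,0.8682292214126804,2.2803692583453747
pl00039,sp0003,plot05,1.9663448117331808,0.7893596891347097,2.1735362080615896
pl00049,sp0003,plot06,NA,0.7564617046103872,2.313612347457719
pl00003,sp0004,plot01,1.6499992886178967,0.3846278903095728,1.4717407382037184
pl00011,sp0004,plot02,1.7142767222652635,0.2902777929167604,1.447741776464294
pl00021,sp0004,plot03,1.6440773810746228,0.22877856864750934,NA
pl00030,sp0005,plot04,2.0057203139231805,0.9294493446976275,1.9743959908145803
pl00040,sp0005,plot05,2.039273092243928,0.9335884295402055,1.925838177773825
pl00050,sp0005,plot06,2.0017055316435233,0.9502530446752958,1.9855752642285251
pl00004,sp0006,plot01,2.103495521530659,0.8756292357008163,1.82304033642713
pl00012,sp0006,plot02,2.0940094912455236,0.9605277100567772,1.951453552993278
pl00022,sp0006,plot03,1.9480321464506005,0.7808600816042724,1.9164861617601712
pl00031,sp0006,plot04,2.3366159314954658,1.2292726173058364,2.2374898280493944
pl00041,sp0006,plot05,NA,1.1201079826850158,2.127431006290432
pl00051,sp0006,plot06,2.2896465945136426,1.078145563950414,2.0217929795543848
pl00005,sp0007,plot01,2.014570665009078,0.5403557847356815,1.9269472706817192
pl00013,sp0007,plot02,2.039853131990496,0.5062963357956834,1.9573577620921658
pl00023,sp0007,plot03,1.9677274145434693,0.5096345613373219,1.9061371208885145
pl00032,sp0007,plot04,NA,0.8608191159441436,2.2604438068070776
pl00042,sp0007,plot05,2.168727370607301,0.7457328256805825,2.1998565725282786
pl00052,sp0007,plot06,2.2547972212895138,NA,NA
pl00006,sp0008,plot01,NA,NA,1.9505943313522318
pl00014,sp0008,plot02,2.119887884645021,0.8324932769178556,1.8718506289566244
pl00024,sp0008,plot03,2.089094582744301,0.7825860940836613,1.8468592087037794
pl00033,sp0008,plot04,2.347953998380089,1.1342114068098978,2.2577532627465997
pl00043,sp0008,plot05,2.3910055808688186,1.1289416017875231,2.162193496381686
pl00053,sp0008,plot06,2.353735725997454,1.0788737787279086,2.1716600812191023
pl00015,sp0009,plot02,2.2938449853767113,0.5769035723551651,1.6521007006692436
pl00034,sp0009,plot04,2.550038248468281,0.8372856038308614,NA
pl00044,sp0009,plot05,2.4748060735524016,0.8418729847073433,1.9649789090144285
pl00054,sp0009,plot06,2.4907324857016233,0.7512544946420965,1.9107795085937742
pl00007,sp0010,plot01,2.1304535681641688,0.5110924154856626,1.5697398575533092
pl00016,sp0010,plot02,2.0804023268955714,0.4696072742732425,1.5371981555710954
pl00035,sp0010,plot04,NA,0.7096321224282273,1.9030903916763484
pl00045,sp0010,plot05,2.385429142916012,0.659881577853759,1.8326071311737275
pl00055,sp0010,plot06,2.4328255240166228,0.670588670067736,1.7863167307826409
pl00008,sp0011,plot01,2.0927199019276133,0.7594569624658167,1.98659137340246
pl00017,sp0011,plot02,2.0010137681378617,0.7099151964384671,1.762047455525629
pl00025,sp0011,plot03,2.028841647955363,0.6390464393706984,1.8604819135871007
pl00036,sp0011,plot04,2.4132206014734328,1.0448308392248975,2.1158192880566813
pl00046,sp0011,plot05,2.307188166958436,1.0615116768508084,2.1079528685027236
pl00056,sp0011,plot06,2.23968068114834,0.9880942309732127,2.1376319972011264
pl00009,sp0012,plot01,2.0166891428275475,0.31649569552818146,1.5175628980524232
pl00018,sp0012,plot02,NA,0.22365221270043295,1.5274674772100962
pl00026,sp0012,plot03,1.970753228198783,0.14146622838501588,1.3451001009497916
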