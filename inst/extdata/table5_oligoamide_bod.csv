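sample,thod,bod5,bod10,bod21,dt5,dt10,dt21
DAF,NA,0.01,0.05,0.05,0.10,0.36,0.37
DAF-AA,NA,0.01,0.05,0.05,0.41,1.44,1.59
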