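area,year,mammal_videos,human_videos
RYER,1,639,869
RYER,2,954,952
RYER,3,885,1288
HWS,1,1309,25
HWS,2,1218,37
HWS,3,1319,34
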