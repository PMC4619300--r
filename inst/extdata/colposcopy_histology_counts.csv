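impression,NORMAL,CIN1,CIN2,CIN3
NORMAL,9,6,2,0
LOW,1,2,2,0
HIGH,3,10,5,6
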