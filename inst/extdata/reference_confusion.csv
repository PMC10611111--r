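class,size,EOA,DCD,CTRL
EOA,18,61.4,21.9,16.6
DCD,13,3.8,82.5,13.7
CTRL,29,4.3,1.2,94.5
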