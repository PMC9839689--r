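{"fx":1000,"fy":1000,"ox":255.5,"oy":255.5,"depth_scale":0.001,"depth_invalid":0}
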