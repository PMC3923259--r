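{"family":"weibull","lambda":0.00468,"beta":1.49,"p":0.97893723700809,"n":64,"tau":529,"seed":20140203,"unit":"weeks"}
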