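child	parent
GO:0006006	GO:0019318
GO:0019318	GO:0005975
GO:0005975	GO:0008152
GO:0046395	GO:0008152
GO:0006635	GO:0046395
GO:0016491	GO:0003824
GO:0016614	GO:0016491
GO:0016620	GO:0016491
GO:0003746	GO:0003824
GO:0016765	GO:0003824
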