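term	weight
(Intercept)	-69.31418341
fickett	  5.18940604
log_orf	 28.49711183
orf_coverage	  3.69638909
complete	  3.36081666
pI	 -0.51441807
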