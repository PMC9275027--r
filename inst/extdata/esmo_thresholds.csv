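form,band,grade,hr_lower_max,gain_min,source
2a,<=12mo,4,0.65,3,framework_default
2a,<=12mo,3,0.65,2.5,framework_default
2a,<=12mo,2,0.70,1.5,framework_default
2a,12-24mo,4,0.70,5,framework_default
2a,12-24mo,3,0.70,3,framework_default
2a,12-24mo,2,0.75,1.5,framework_default
2a,>24mo,4,0.70,9,verified
2a,>24mo,3,0.70,6,framework_default
2a,>24mo,2,0.75,4,framework_default
2b,<=6mo,3,0.65,1.5,framework_default
2b,<=6mo,2,0.75,1.5,framework_default
2b,>6mo,3,0.65,3,verified
2b,>6mo,2,0.75,1.5,framework_default
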