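horse,limb,slope,slope_se,r,excluded
1,LF,-0.012,9.13e-5,-0.16,FALSE
1,RF,NA,NA,NA,TRUE
1,LH,-0.010,7.13e-5,-0.23,FALSE
1,RH,-0.011,7.20e-5,-0.24,FALSE
2,LF,-0.0098,6.87e-5,-0.18,FALSE
2,RF,-0.0094,6.16e-5,-0.29,FALSE
2,LH,-0.0094,5.83e-5,-0.29,FALSE
2,RH,-0.0094,5.53e-5,-0.35,FALSE
3,LF,-0.0090,6.87e-5,-0.30,FALSE
3,RF,-0.0090,6.27e-5,-0.34,FALSE
3,LH,-0.0094,5.41e-5,-0.33,FALSE
3,RH,-0.0087,5.49e-5,-0.43,FALSE
4,LF,-0.0086,5.89e-5,-0.36,FALSE
4,RF,-0.0082,7.12e-5,-0.29,FALSE
4,LH,-0.0084,5.70e-5,-0.32,FALSE
4,RH,-0.0077,6.39e-5,-0.30,FALSE
5,LF,-0.0074,8.36e-5,-0.22,FALSE
5,RF,-0.0072,8.65e-5,-0.24,FALSE
5,LH,-0.0074,7.14e-5,-0.28,FALSE
5,RH,-0.0076,6.66e-5,-0.30,FALSE
6,LF,-0.0069,7.25e-5,-0.31,FALSE
6,RF,-0.0057,8.80e-5,-0.14,FALSE
6,LH,-0.0048,7.27e-5,-0.32,FALSE
6,RH,-0.0048,7.39e-5,-0.40,FALSE
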