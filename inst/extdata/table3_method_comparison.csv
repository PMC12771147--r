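sample_id,mean_uvvis,sd_uvvis,mean_dia,sd_dia,n,printed_f,printed_p_f,printed_t,printed_p_t,printed_re_pct
A1,3.20e-3,1.00e-4,3.36e-3,1.52e-4,3,0.42,0.60,2.50,0.13,5.20
A2,5.16e-3,4.16e-4,4.83e-3,4.93e-4,3,0.71,0.83,1.79,0.21,6.45
A3,1.33e-3,2.00e-3,1.26e-3,1.52e-4,3,1.85,0.70,1.00,0.42,5.00
A4,8.00e-4,1.00e-4,7.66e-4,1.52e-4,3,0.43,0.60,0.50,0.66,4.16
A5,1.46e-3,2.08e-4,1.56e-3,1.00e-4,3,1.85,0.70,0.86,0.47,6.81
A6,5.00e-4,1.00e-4,5.00e-4,1.00e-4,3,1.00,1.00,0.00,1.00,0.00
A7,1.30e-3,1.00e-4,1.20e-3,1.00e-4,3,1.00,1.00,0.86,0.47,7.69
A8,7.00e-4,1.00e-4,7.33e-4,1.52e-4,3,0.42,0.60,0.25,0.82,4.76
A9,4.46e-3,3.05e-4,4.56e-3,6.02e-4,3,0.25,0.40,0.57,0.62,2.23
A10,2.50e-3,1.00e-4,2.36e-3,2.08e-4,3,0.23,0.37,2.00,0.18,5.33
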