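hepatocyte_sample,dose_uM,time_h,compound,concentration_uM
HL-1,1,24,meiqx,0.05
HL-1,1,24,meiqx_n2_gl,0.02
HL-1,1,24,meiqx_n2_so3h,0.13
HL-1,1,24,oxo_meiqx,0.05
HL-1,1,24,c_hydroxy_meiqx,0.41
HL-1,1,24,hon_meiqx_n2_gl,0.08
HL-1,10,24,meiqx,1.4
HL-1,10,24,meiqx_n2_gl,0.9
HL-1,10,24,meiqx_n2_so3h,2.3
HL-1,10,24,oxo_meiqx,1.2
HL-1,10,24,c_hydroxy_meiqx,0.9
HL-1,10,24,hon_meiqx_n2_gl,0.8
HL-1,50,24,meiqx,29
HL-1,50,24,meiqx_n2_gl,1
HL-1,50,24,meiqx_n2_so3h,6
HL-1,50,24,oxo_meiqx,6.5
HL-1,50,24,c_hydroxy_meiqx,1.5
HL-1,50,24,hon_meiqx_n2_gl,1
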