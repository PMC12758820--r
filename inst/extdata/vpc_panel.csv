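name,khl,khl_lo,khl_hi,mw,density,diffusion_d
isoprene,1.14e-2,1.02e-2,1.28e-2,68.12,0.681,
ethyl acetate,6.98e-3,6.28e-3,7.76e-3,88.11,0.902,
pentanal,2.54e-3,2.27e-3,2.85e-3,86.13,0.810,
(Z)-3-hexen-1-ol,7.49e-4,,,100.16,0.848,
(E)-2-hexenal,6.25e-4,5.76e-4,6.78e-4,98.14,0.846,
alpha-pinene,3.84e-5,3.42e-5,4.25e-5,136.23,0.858,
(Z)-3-hexenyl acetate,2.71e-5,2.70e-5,2.72e-5,142.2,0.897,
eucalyptol,1.49e-5,1.34e-5,1.65e-5,154.25,0.9225,
linalool,7.48e-6,7.32e-6,7.64e-6,154.25,0.858,
indole,1.88e-6,1.78e-6,1.99e-6,117.15,1.22,
beta-caryophyllene,1.92e-7,1.88e-7,1.96e-7,204.36,0.905,
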