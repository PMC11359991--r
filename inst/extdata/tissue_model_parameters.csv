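tissue,eps_inf,eps_s,tau_ps,alpha
muscle,4,51.47,6.36,0.1
liver,4,46.99,6.36,0.1
heart,4,64.02,6.36,0.1
kidney,4,49.59,6.36,0.1
fat,2.5,3.930,6.36,0.1
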