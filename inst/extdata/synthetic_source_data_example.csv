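figure_panel,cell_id,condition,value
ppr,c01,led_20hz,0.71
ppr,c02,led_20hz,0.88
ppr,c03,led_20hz,0.94
ppr,c04,led_20hz,0.79
ppr,c05,led_20hz,0.66
nmda_drug,c06,ctrl,-98.4
nmda_drug,c06,ifenprodil,-55.1
nmda_drug,c07,ctrl,-120.7
nmda_drug,c07,ifenprodil,-70.3
nmda_drug,c08,ctrl,-87.9
nmda_drug,c08,ifenprodil,-44.2
nmda_drug,c09,ctrl,-105.2
nmda_drug,c09,ifenprodil,-61.8
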