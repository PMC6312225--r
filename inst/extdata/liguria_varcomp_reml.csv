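Component,Level,Variance
wb,,0.031683
year,,0.000000
surveyor,,0.000000
wb_in_year,Capo Mortola,0.001691
wb_in_year,Laigueglia-Albenga,0.003284
wb_in_year,Genova-Camogli,0.013276
wb_in_year,Portofino,0.001302
wb_in_year,Punta Mesco,0.003444
wb_in_year,Cinque Terre,0.004810
wb_in_year,Portovenere,0.003429
residual,,0.004404
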