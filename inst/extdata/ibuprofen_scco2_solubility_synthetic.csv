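temperature_K,pressure_bar,y_p_kg_per_kg
313,120,0.0220
313,140,0.0230
313,160,0.0260
313,200,0.0400
323,120,0.0220
323,140,0.0235
323,160,0.0280
323,200,0.0440
333,120,0.0220
333,140,0.0250
333,160,0.0320
333,200,0.0480
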