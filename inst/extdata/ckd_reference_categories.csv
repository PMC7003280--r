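category,weighted_count,rate_pct
deficiency-tonifying,1233,29.91
heat-clearing,1027,24.91
dampness-draining diuretic,410,9.94
hemostatic,198,4.8
astringent,170,4.12
qi-regulating,169,4.1
blood-activating and stasis-resolving,162,3.93
cough-suppressing and panting-calming,151,3.66
exterior-releasing,134,3.25
digestant,115,2.79
wind-dampness dispelling,94,2.28
dampness-resolving,83,2.01
purgative,70,1.7
nerve-soothing,55,1.33
interior-warming,27,0.65
liver-wind calming,24,0.58
antitoxin-insecticide-antipruritic,1,0.02
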