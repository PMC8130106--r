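name,unit_cost_eur
CPAP,151.68
nasal_mask,35.48
nasal_gel_mask,56.00
oronasal_mask,93.78
humidifier,94.27
tubes,12.63
accessory_mask,2.65
filter,5.50
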