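item,quantity
CPAP,21
nasal_mask,45
nasal_gel_mask,3
oronasal_mask,5
humidifier,4
tubes,3
accessory_mask,12
filter,7
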