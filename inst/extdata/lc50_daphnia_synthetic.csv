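pesticide,lc50_ugL
chlorpyrifos,1.0
diazinon,0.96
malathion,1.8
cypermethrin,0.3
deltamethrin,0.56
carbaryl,14.6
carbendazim,130
iprobenfos,4200
metribuzin,41000
atrazine,36000
lindane,880
carbofuran,38.6
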