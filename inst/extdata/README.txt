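lc50_daphnia_synthetic.csv

A SYNTHETIC stand-in reference table of 48-h acute Daphnia magna LC50 values
(micrograms per litre) for pesticides commonly detected in agricultural
catchments. The numbers are order-of-magnitude representative of the public
ecotoxicology literature but are NOT a curated compilation; replace this file
with a curated LC50 table for any real analysis. Schema: pesticide,lc50_ugL.
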