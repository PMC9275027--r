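drug_name,price_per_mg,currency
pazopanib,0.57,USD
sunitinib,3.60,USD
nivolumab,28.50,USD
ipilimumab,157.00,USD
axitinib,33.00,USD
avelumab,9.80,USD
pembrolizumab,52.00,USD
lenvatinib,22.00,USD
cabozantinib,6.20,USD
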