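treatment,ec50_mg_L
Product 4,22.97
Pro + NOP + BP,41.11
Pro,46.31
NOP,114.9
BP,1427
Product 5,28.99
Pen + Fluf + SN,69.98
Pen + Fluf,131.7
SN,399.4
Product 6,9.14
Teb + Pro + NDA,12.16
Teb + Pro,45.84
NDA,79.8
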