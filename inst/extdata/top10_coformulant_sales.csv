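cas,name,sales_tonnes
7732-18-5,Water,22962
130498-22-5,Wheat flour,3580
14433-76-2,"N,N-Dimethyldecan-1-amide",3160
64742-94-5,"Solvent naphtha (petroleum), heavy arom. (C9-C16)",1819
1189173-42-9,"Hydrocarbons, C10, aromatics, <1% naphthalene",1222
57-55-6,"Propane-1,2-diol",1078
61791-12-6,"Castor oil, ethoxylated",974
85586-25-0,"Fatty acids, rape-oil, Me esters",787
186817-80-1,"Propanoic acid, 2-hydroxy-, 2-ethylhexyl ester, (2S)-",723
7783-20-2,Ammonium sulphate,508
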