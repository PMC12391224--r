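well_id,group,cells,heat_per_cell_uJ
B1,No Cells,0,0.25
C1,No Cells,0,0.03
D1,No Cells,0,0.31
E1,No Cells,0,0.66
B2,No Cells,0,0.74
C2,No Cells,0,0.56
D2,No Cells,0,0.18
E2,No Cells,0,0.25
B3,Cells Only,150000,3.26
C3,Cells Only,150000,2.83
D3,Cells Only,150000,3.00
E3,Cells Only,150000,2.76
B4,Cells Only,150000,3.45
C4,Cells Only,150000,3.97
D4,Cells Only,150000,3.00
E4,Cells Only,150000,1.99
B5,Cells + Glucose,150000,1.54
C5,Cells + Glucose,150000,2.08
D5,Cells + Glucose,150000,3.03
E5,Cells + Glucose,150000,3.11
B6,Cells + Glucose,150000,2.65
C6,Cells + Glucose,150000,4.34
D6,Cells + Glucose,150000,2.61
E6,Cells + Glucose,150000,2.98
B7,Cells + Glutamine,150000,1.42
C7,Cells + Glutamine,150000,0.68
D7,Cells + Glutamine,150000,2.37
E7,Cells + Glutamine,150000,2.23
B8,Cells + Glutamine,150000,1.82
C8,Cells + Glutamine,150000,1.77
D8,Cells + Glutamine,150000,2.07
E8,Cells + Glutamine,150000,2.83
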