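lhs_label,rhs_label,support_pct,confidence_pct,lift
Radix Astragali,Rhizoma Dioscoreae,51.51,88.51,1.15
Poria,Rhizoma Dioscoreae,47.16,85.45,1.11
Rhizoma Atractylodis Macrocephalae,Rhizoma Dioscoreae,46.49,86.34,1.12
Fructus Corni,Rhizoma Dioscoreae,44.82,95.71,1.24
Radix Pseudostellariae,Rhizoma Dioscoreae,42.14,88.73,1.15
Rhizoma Atractylodis Macrocephalae;Radix Astragali,Rhizoma Dioscoreae,41.14,90.44,1.17
Rhizoma Atractylodis Macrocephalae;Rhizoma Dioscoreae,Radix Astragali,41.14,88.49,1.52
Rhizoma Atractylodis Macrocephalae;Poria,Rhizoma Dioscoreae,39.13,89.31,1.16
Poria;Radix Astragali,Rhizoma Dioscoreae,38.13,91.94,1.19
Rhizoma Atractylodis Macrocephalae;Poria,Radix Astragali,37.46,85.50,1.47
Poria;Radix Astragali,Rhizoma Atractylodis Macrocephalae,37.46,90.32,1.68
Root of Snow of June;Radix Astragali,Rhizoma Dioscoreae,36.45,91.60,1.19
Radix Astragali;Radix Pseudostellariae,Rhizoma Dioscoreae,34.45,90.35,1.17
Spreading Hedyotis Herb;Radix Astragali,Rhizoma Dioscoreae,34.45,89.57,1.16
Rhizoma Atractylodis Macrocephalae;Poria;Radix Astragali,Rhizoma Dioscoreae,34.11,91.07,1.18
Rhizoma Atractylodis Macrocephalae;Poria;Rhizoma Dioscoreae,Radix Astragali,34.11,87.18,1.50
Poria;Radix Astragali;Rhizoma Dioscoreae,Rhizoma Atractylodis Macrocephalae,34.11,89.47,1.66
Root of Snow of June;Rhizoma Atractylodis Macrocephalae,Radix Astragali,33.78,87.83,1.51
Root of Snow of June;Rhizoma Atractylodis Macrocephalae,Rhizoma Dioscoreae,33.78,87.83,1.14
Radix Astragali;Fructus Corni,Rhizoma Dioscoreae,33.44,95.24,1.23
Root of Snow of June;Poria,Rhizoma Dioscoreae,33.44,89.29,1.16
Root of Snow of June;Fructus Corni,Rhizoma Dioscoreae,32.44,95.10,1.23
Root of Snow of June;Poria,Rhizoma Atractylodis Macrocephalae,32.44,86.61,1.61
Spreading Hedyotis Herb;Fructus Corni,Rhizoma Dioscoreae,31.44,94.95,1.23
Rhizoma Atractylodis Macrocephalae;Fructus Corni,Rhizoma Dioscoreae,31.10,95.88,1.24
Root of Snow of June;Rhizoma Atractylodis Macrocephalae;Radix Astragali,Rhizoma Dioscoreae,30.77,91.09,1.18
Root of Snow of June;Rhizoma Atractylodis Macrocephalae;Rhizoma Dioscoreae,Radix Astragali,30.77,91.09,1.57
Rhizoma Atractylodis Macrocephalae;Radix Pseudostellariae,Rhizoma Dioscoreae,30.43,91.00,1.18
Rhizoma Atractylodis Macrocephalae;Fructus Corni,Radix Astragali,30.10,92.78,1.59
Radix Astragali;Fructus Corni,Rhizoma Atractylodis Macrocephalae,30.10,85.71,1.59
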