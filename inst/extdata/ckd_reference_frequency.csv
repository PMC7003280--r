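herb,pinyin,count,relative_frequency
Rhizoma Dioscoreae,Shanyao,231,0.773
Spreading Hedyotis Herb,Baihuasheshecao,196,0.656
Root of Snow of June,Baimagu,175,0.585
Radix Astragali,Huangqi,174,0.582
Poria,Fulin,166,0.555
Rhizoma Atractylodis Macrocephalae,Baizhu,162,0.542
Radix Pseudostellariae,Taizishen,143,0.478
Fructus Corni,Shanzhuyu,140,0.468
Radix Rehmanniae,Shengdihuang,102,0.341
Fructus Lycii,Gouqizi,100,0.334
Flos Carthami,Honghua,96,0.321
Common Sage Herb,Lizhicao,86,0.288
Pericarpium Citri Reticulatae,Chenpi,84,0.281
Cortex Phellodendri,Huangbai,83,0.278
Semen Coicis,Yiyiren,80,0.268
Rhizoma Imperatae,Baimaogen,79,0.264
Rhizoma Anemarrhenae,Zhimu,78,0.261
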