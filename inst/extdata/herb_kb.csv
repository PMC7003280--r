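canonical_name,pinyin,aliases,property,tastes,meridians,category,components
Rhizoma Dioscoreae,Shanyao,Dioscoreae Rhizoma,neutral,sweet,Spleen;Lung;Kidney,deficiency-tonifying,
Spreading Hedyotis Herb,Baihuasheshecao,Herba Hedyotis Diffusae;Oldenlandia,cold,bitter;sweet,Stomach;Large Intestine;Small Intestine,heat-clearing,
Root of Snow of June,Baimagu,Serissa Root;Liuyuexue,cool,bitter;pungent,Liver;Spleen,heat-clearing,
Radix Astragali,Huangqi,Astragali Radix;Astragalus Root,warm,sweet,Spleen;Lung,deficiency-tonifying,
Poria,Fulin,Fuling;Poria Cocos,neutral,sweet;bland,Heart;Spleen;Kidney,dampness-draining diuretic,
Rhizoma Atractylodis Macrocephalae,Baizhu,Atractylodis Macrocephalae Rhizoma,warm,sweet;bitter,Spleen;Stomach,deficiency-tonifying,
Radix Pseudostellariae,Taizishen,Pseudostellariae Radix,neutral,sweet;bitter,Spleen;Lung,deficiency-tonifying,
Fructus Corni,Shanzhuyu,Corni Fructus;Cornus,warm,sour;astringent,Liver;Kidney,astringent,
Radix Rehmanniae,Shengdihuang,Rehmanniae Radix;Dihuang,cold,sweet;bitter,Heart;Liver;Kidney,heat-clearing,
Fructus Lycii,Gouqizi,Lycii Fructus;Goji,neutral,sweet,Liver;Kidney,deficiency-tonifying,
Flos Carthami,Honghua,Carthami Flos;Safflower,warm,pungent,Heart;Liver,blood-activating and stasis-resolving,
Common Sage Herb,Lizhicao,Herba Salviae Plebeiae,cool,bitter;pungent,Lung;Bladder,heat-clearing,
Pericarpium Citri Reticulatae,Chenpi,Citri Reticulatae Pericarpium;Tangerine Peel,warm,pungent;bitter,Spleen;Lung,qi-regulating,
Cortex Phellodendri,Huangbai,Phellodendri Cortex,cold,bitter,Kidney;Bladder,heat-clearing,
Semen Coicis,Yiyiren,Coicis Semen;Job's Tears,cool,sweet;bland,Spleen;Stomach;Lung,dampness-draining diuretic,
Rhizoma Imperatae,Baimaogen,Imperatae Rhizoma,cold,sweet,Lung;Stomach;Bladder,hemostatic,
Rhizoma Anemarrhenae,Zhimu,Anemarrhenae Rhizoma,cold,bitter;sweet,Lung;Stomach;Kidney,heat-clearing,
Radix Salviae Miltiorrhizae,Danshen,Salviae Miltiorrhizae Radix,cool,bitter,Heart;Liver,blood-activating and stasis-resolving,
Radix Angelicae Sinensis,Danggui,Angelicae Sinensis Radix,warm,sweet;pungent,Liver;Heart;Spleen,deficiency-tonifying,
Rhizoma Alismatis,Zexie,Alismatis Rhizoma,cold,sweet;bland,Kidney;Bladder,dampness-draining diuretic,
Cortex Moutan,Mudanpi,Moutan Cortex,cool,bitter;pungent,Heart;Liver;Kidney,heat-clearing,
Radix Paeoniae Alba,Baishao,Paeoniae Radix Alba,cool,bitter;sour,Liver;Spleen,deficiency-tonifying,
Radix Glycyrrhizae,Gancao,Glycyrrhizae Radix;Licorice Root,neutral,sweet,Heart;Lung;Spleen;Stomach,deficiency-tonifying,
Semen Cuscutae,Tusizi,Cuscutae Semen,neutral,pungent;sweet,Liver;Kidney;Spleen,deficiency-tonifying,
Cortex Eucommiae,Duzhong,Eucommiae Cortex,warm,sweet,Liver;Kidney,deficiency-tonifying,
Herba Leonuri,Yimucao,Leonuri Herba,cool,bitter;pungent,Heart;Liver;Bladder,blood-activating and stasis-resolving,
Radix Achyranthis Bidentatae,Niuxi,Achyranthis Bidentatae Radix,neutral,bitter;sour,Liver;Kidney,blood-activating and stasis-resolving,
Herba Taxilli,Sangjisheng,Taxilli Herba,neutral,bitter;sweet,Liver;Kidney,wind-dampness dispelling,
Fructus Ligustri Lucidi,Nvzhenzi,Ligustri Lucidi Fructus,cool,sweet;bitter,Liver;Kidney,deficiency-tonifying,
Herba Ecliptae,Mohanlian,Ecliptae Herba,cold,sweet;sour,Liver;Kidney,deficiency-tonifying,
Rhizoma Chuanxiong,Chuanxiong,Chuanxiong Rhizoma,warm,pungent,Liver;Gallbladder;Pericardium,blood-activating and stasis-resolving,
Semen Persicae,Taoren,Persicae Semen;Peach Kernel,neutral,bitter;sweet,Heart;Liver;Large Intestine,blood-activating and stasis-resolving,
Radix Codonopsis,Dangshen,Codonopsis Radix,neutral,sweet,Spleen;Lung,deficiency-tonifying,
Herba Agrimoniae,Xianhecao,Agrimoniae Herba,neutral,bitter;astringent,Heart;Liver,hemostatic,
Radix Scutellariae,Huangqin,Scutellariae Radix,cold,bitter,Lung;Gallbladder;Stomach;Large Intestine,heat-clearing,
Rhizoma Coptidis,Huanglian,Coptidis Rhizoma,cold,bitter,Heart;Spleen;Stomach;Liver;Gallbladder;Large Intestine,heat-clearing,
Fructus Crataegi,Shanzha,Crataegi Fructus;Hawthorn,warm,sour;sweet,Spleen;Stomach;Liver,digestant,
Massa Medicata Fermentata,Shenqu,Liushenqu,warm,sweet;pungent,Spleen;Stomach,digestant,
Rhizoma Pinelliae,Banxia,Pinelliae Rhizoma,warm,pungent,Spleen;Stomach;Lung,cough-suppressing and panting-calming,
Semen Armeniacae Amarum,Xingren,Armeniacae Semen Amarum,warm,bitter,Lung;Large Intestine,cough-suppressing and panting-calming,
Radix Saposhnikoviae,Fangfeng,Saposhnikoviae Radix,warm,pungent;sweet,Bladder;Liver;Spleen,exterior-releasing,
Ramulus Cinnamomi,Guizhi,Cinnamomi Ramulus,warm,pungent;sweet,Heart;Lung;Bladder,exterior-releasing,
Radix et Rhizoma Rhei,Dahuang,Rhei Radix et Rhizoma;Rhubarb,cold,bitter,Spleen;Stomach;Large Intestine;Liver;Pericardium,purgative,
Semen Ziziphi Spinosae,Suanzaoren,Ziziphi Spinosae Semen,neutral,sweet;sour,Liver;Gallbladder;Heart,nerve-soothing,
Concha Ostreae,Muli,Ostreae Concha;Oyster Shell,cool,salty;astringent,Liver;Gallbladder;Kidney,liver-wind calming,
Herba Plantaginis,Cheqiancao,Plantaginis Herba,cold,sweet,Liver;Kidney;Lung;Small Intestine,dampness-draining diuretic,
Herba Artemisiae Scopariae,Yinchen,Artemisiae Scopariae Herba,cool,bitter;pungent,Spleen;Stomach;Liver;Gallbladder,dampness-draining diuretic,
Fructus Amomi,Sharen,Amomi Fructus,warm,pungent,Spleen;Stomach;Kidney,dampness-resolving,
Rhizoma Atractylodis,Cangzhu,Atractylodis Rhizoma,warm,pungent;bitter,Spleen;Stomach;Liver,dampness-resolving,
Rhizoma Zingiberis,Ganjiang,Zingiberis Rhizoma;Dried Ginger,hot,pungent,Spleen;Stomach;Kidney;Heart;Lung,interior-warming,
Fructus Evodiae,Wuzhuyu,Evodiae Fructus,hot,pungent;bitter,Liver;Spleen;Stomach;Kidney,interior-warming,
Semen Euryales,Qianshi,Euryales Semen,neutral,sweet;astringent,Spleen;Kidney,astringent,
Liuwei Dihuang Wan,,Six-Ingredient Rehmannia Pill,,,,,Rhizoma Dioscoreae;Fructus Corni;Radix Rehmanniae;Poria;Rhizoma Alismatis;Cortex Moutan
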