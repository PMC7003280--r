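prescription_id,patient_id,herbs
p001,u01,Huangqi;Shanyao;Baizhu;Fulin;Baihuasheshecao;Shanzhuyu
p002,u01,Huangqi;Shanyao;Baizhu;Fuling;Taizishen;Baimagu
p003,u02,Liuwei Dihuang Wan;Huangqi;Baihuasheshecao
p004,u02,Shanyao;Shanzhuyu;Shengdihuang;Zexie;Mudanpi;Fulin
p005,u03,Huangqi;Baizhu;Fulin;Baimagu;Yiyiren;Chenpi
p006,u03,Huangqi;Shanyao;Baizhu;Shanzhuyu;Gouqizi;Nvzhenzi
p007,u04,Shanyao;Baihuasheshecao;Baimagu;Huangbai;Zhimu;Shengdihuang
p008,u04,Huangqi;Shanyao;Taizishen;Fulin;Baizhu;Danshen
p009,u05,Shanyao;Shanyao;Huangqi;Baimaogen;Xianhecao
p010,u05,Huangqi;Shanyao;Baizhu;Fulin;Baimagu;Baihuasheshecao;Shanzhuyu
p011,u06,Chenpi;Banxia;Fulin;Cangzhu;Yinchen
p012,u06,Huangqi;Shanyao;Duzhong;Sangjisheng;Tusizi;Niuxi
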