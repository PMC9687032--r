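index,name,class,formula,calc_mz,obs_mz,fragments,first_in_sf,formula_suspect
1,"Gallic acid",phenolic acid,C7H6O5,169.0134,169.0137,125.02,FALSE,FALSE
2,"Vanillic acid",phenolic acid,C8H8O4,167.0343,167.0344,108.02;152.011,FALSE,FALSE
3,"Isopropyl 3-(3,4-dihydroxyphenyl)-2-hydroxypropanoate",phenolic acid,C12H16O5,239.0929,239.0925,173.03;123.04,TRUE,FALSE
4,"3,4-Dihydroxyphenylglycol",phenolic acid,C8H10O4,169.0500,169.0506,151.03;123.00,TRUE,FALSE
5,"Scopoletin",phenolic acid,C10H8O4,191.0349,191.0350,175.03;147.04,TRUE,FALSE
6,"Caffeic acid 4-sulfate",phenolic acid,C9H8O7S,258.9899,258.9912,215.00;179.03;135.04,TRUE,FALSE
7,"Cinnamoyl glucose",phenolic acid,C15H18O7,309.0974,309.0974,147.04;131.04;103.05,TRUE,FALSE
8,"3'-O-Methylcatechin",flavonoid,C16H16O6,303.0862,303.0868,271.07;163.05,FALSE,FALSE
9,"4',7-Dihydroxyisoflavone",flavonoid,C15H10O4,253.0493,253.0500,225.05;197.06;143.03,TRUE,FALSE
10,"Naringenin",flavonoid,C15H12O5,271.0581,271.0606,229.05;177.01;151.00;119.06,TRUE,FALSE
11,"Phloroglucinol",tannin,C6H6O3,125.0237,125.0238,97.04,FALSE,FALSE
12,"Fucophlorethol-A",tannin,C18H14O9,373.0557,373.0559,247.05;233.02;229.07;125.03,FALSE,FALSE
13,"Bifuhalol",tannin,C12H10O7,264.0345,264.0348,247.03;141.07;111.03;123.01;125.03,FALSE,FALSE
14,"Diphlorethohydroxycarmalol",tannin,C24H15O13,511.0510,511.0506,385.00,TRUE,TRUE
15,"Dibenzodioxin-1,3,6,8-tetraol",tannin,C12H7O6,246.9919,246.9914,203.05;121.01,TRUE,FALSE
16,"Fucophlorethol",tannin,C36H26O14,680.1154,680.1179,610.05;601.03;495.07;469.06;229.03,TRUE,FALSE
17,"Glycyrrhizin",terpene,C42H62O16,821.3951,821.3959,777.40;627.35;469.33;451.32,FALSE,FALSE
18,"beta-Glycyrrhetinic acid",terpene,C30H46O4,469.3330,469.3317,451.32;423.32;409.31,FALSE,FALSE
19,"Isololiolide",terpene,C11H16O3,195.1021,195.1021,161.09;179.10;133.10;105.07,FALSE,FALSE
20,"Lupenone",terpene,C30H48O,423.3620,423.3626,408.33;381.33;365.27;257.24,FALSE,FALSE
21,"Fumaric acid",carboxylic acid,C4H4O4,115.0050,115.0037,71.01,FALSE,FALSE
22,"Threonic acid",carboxylic acid,C4H8O5,135.0290,135.0299,117.01;91.04;72.99,FALSE,FALSE
23,"Cinnamic acid",carboxylic acid,C9H8O2,147.0442,147.0452,129.03;103.05,FALSE,FALSE
24,"Gentisic acid",carboxylic acid,C7H6O4,153.0187,153.1287,152.74;108.07;81.05,FALSE,FALSE
25,"Behenic acid",carboxylic acid,C22H44O2,339.3268,339.3263,321.31;295.33;211.24,FALSE,FALSE
26,"Kainic acid",carboxylic acid,C10H15NO4,212.0922,212.0922,168.2;194.1;150.2,FALSE,FALSE
27,"Mannuronic acid",carboxylic acid,C6H10O7,193.0353,193.0348,175.02;103.00;72.99,FALSE,FALSE
28,"Diethyl phthalate",carboxylic acid,C12H14O4,221.0818,221.0813,193.08;177.09;149.09;121.02,FALSE,FALSE
29,"Vanillylmandelic acid",carboxylic acid,C9H10O5,197.0449,197.0450,153.05;137.02;123.04;107.01,FALSE,FALSE
30,"Phthalic acid",carboxylic acid,C8H6O4,165.0188,165.0187,121.126;119.15;58.91,FALSE,FALSE
31,"3-Oxooctanoic acid",carboxylic acid,C8H14O3,157.0863,157.0876,139.07;113.09;97.06,FALSE,FALSE
32,"D-Glucaric acid derivate",carboxylic acid,C12H14O10,317.0544,317.0509,209.08,FALSE,FALSE
33,"Fukic acid",carboxylic acid,C11H12O8,271.0459,271.0453,227.05;197.04;179.03,FALSE,FALSE
34,"Mono-(3-carboxypropyl) phthalate",carboxylic acid,C12H12O6,251.0556,251.0555,233.04;207.06;165.01,FALSE,FALSE
35,"Azelaic acid",carboxylic acid,C9H16O4,187.0969,188.0976,187.31;124.91;169.20;111.20,FALSE,FALSE
36,"Caprylic acid",fatty acid,C8H15O2,143.1070,143.1072,125.09;99.11;59.01,FALSE,FALSE
37,"Stearic acid",fatty acid,C18H36O2,283.2641,283.2637,265.25;239.27;237.25,FALSE,FALSE
38,"cis-Vaccenic acid",fatty acid,C18H34O2,281.2486,281.2487,263.23;223.17;163.14;71.01,FALSE,FALSE
39,"alpha-Linoleic acid",fatty acid,C18H32O2,279.2331,279.2330,261.22;235.24;233.22,FALSE,FALSE
40,"Oleic acid",fatty acid,C18H34O2,281.2487,281.2486,263.25;181.21;127.25,FALSE,FALSE
41,"Palmitic acid",fatty acid,C16H32O2,255.233,255.233,237.23;211.24;197.22,FALSE,FALSE
42,"Myristic acid",fatty acid,C14H28O2,227.2015,227.2017,209.19;183.21;179.18,FALSE,FALSE
43,"Arachidic acid",fatty acid,C20H40O2,311.2958,311.295,297.04;275.84;200.85,FALSE,FALSE
44,"Eicosapentaenoic acid",fatty acid,C20H30O2,301.2176,301.2173,299.20;283.20;229.15;131.08;71.01,FALSE,FALSE
45,"Arachidonic acid",fatty acid,C20H32O2,303.2333,303.233,285.2218;259.24;257.22,FALSE,FALSE
46,"5,8,11-Eicosatrienoic acid",fatty acid,C20H34O2,305.2491,305.2486,287.23;261.25;207.21,FALSE,FALSE
47,"11,14-Eicosadienoic acid",fatty acid,C20H36O2,307.2643,307.2643,289.25;249.18;233.19;153.09;71.01,FALSE,FALSE
48,"Octadecendioic acid",fatty acid,C18H32O4,311.223,311.2239,299.25;269.24;251.23;223.24,FALSE,FALSE
49,"Methyl arachidonate",fatty acid,C21H34O2,317.2487,317.2486,315.23;301.21;243.17;191.18;121.10;73.02,FALSE,FALSE
50,"13-keto-9Z,11E-Octadecadienoic acid",fatty acid,C18H30O3,293.2125,293.2122,275.20;195.13;113.09,FALSE,FALSE
51,"10-Oxooctadecanoic acid",fatty acid,C18H34O3,297.2436,297.2435,279.23;209.15;141.12;127.11,FALSE,FALSE
52,"10,16-Dihydroxy-palmitic acid",fatty acid,C16H32O4,287.2227,287.2222,269.21;257.21;239.20;185.11,FALSE,FALSE
53,"Vernolic acid",fatty acid,C18H32O3,295.2278,295.2273,277.21;251.23;195.13;127.11,FALSE,FALSE
54,"Octadeca-2,4-dienedioic acid",fatty acid,C18H30O4,309.2072,309.2071,291.19;265.21;247.20,FALSE,FALSE
55,"Palmitaldehyde",fatty acid,C16H32O,239.092,239.0925,237.22;207.21;153.12;127.14,FALSE,FALSE
56,"Myristic aldehyde",fatty acid,C14H28O,211.2064,211.2067,209.19;167.14;127.14;99.11;71.08,FALSE,FALSE
57,"Heptanal",fatty acid,C7H14O,113.0962,113.0972,95.08;85.10,FALSE,FALSE
58,"9-Octadecenal",fatty acid,C18H34O,265.2544,265.2537,249.22;247.24;235.24,FALSE,FALSE
59,"2,4-Decadienal",fatty acid,C10H16O,151.1119,151.1128,133.10;123.11;119.08;93.07,FALSE,FALSE
60,"Nonanal",fatty acid,C9H18O,141.128,141.1285,123.11;113.13;95.08,FALSE,FALSE
61,"Ethyl oleate",fatty acid,C20H38O2,309.2798,309.2799,291.26;281.24;263.23;237.25;45.03,FALSE,FALSE
62,"1-Docosanol",fatty acid,C22H46O,325.3475,325.3476,309.31;307.33;295.33;267.30,FALSE,FALSE
63,"(9R,10S,12Z)-9,10-Dihydroxy-8-oxo-12-octadecenoic acid",fatty acid,C18H32O5,327.2178,327.2177,309.20;283.22;187.09;157.08,FALSE,FALSE
64,"5,8,12-Trihydroxy-9-octadecenoic acid",fatty acid,C18H34O5,329.2338,329.2333,311.22;285.24;267.23;243.12;195.17;145.08,FALSE,FALSE
65,"13-Docosenamide",fatty acid,C22H43NO,336.3274,336.3272,319.30;293.3214;58.02,FALSE,FALSE
66,"Lauric acid",fatty acid,C12H24O2,199.1697,199.1698,181.1062;155.0336,FALSE,FALSE
67,"L-Proline",amino acid,C5H9NO2,114.0560,114.0555,70.06,FALSE,FALSE
68,"Glutamic acid",amino acid,C5H9NO4,146.0451,146.0453,70.06,FALSE,FALSE
69,"D-Histidine",amino acid,C6H9N3O2,154.0628,154.0616,82.3;71.9,FALSE,FALSE
70,"D-Galactose",sugar,C6H12O6,179.0568,179.0555,161.04;143.03;113.02;101.02,FALSE,FALSE
71,"Mannitol",sugar,C6H14O6,181.0712,181.0718,165.01;147.03;129.05;111.00,FALSE,FALSE
72,"Gluconic acid",sugar,C6H12O7,195.0517,195.0504,177.05;159.02;129.05;98.90,FALSE,FALSE
73,"Xylitol",sugar,C5H12O5,151.0618,151.0612,119;131;89.1,FALSE,FALSE
74,"Maltitol",sugar,C12H24O11,343.1248,343.124,283.10;265.09;179.05;161.04;143.03,FALSE,FALSE
75,"4-Octylphenol",other,C14H22O,205.1593,205.1592,135.08;119.05;107.05;93.03,FALSE,FALSE
76,"2,4-Dibromophenol",other,C6H4Br2O,248.8649,248.8550,248.85;168.92,FALSE,FALSE
77,"Dihydroconiferyl alcohol",other,C10H14O3,181.0864,181.0864,163.07;135.04,FALSE,FALSE
78,"Dihydroxyphenylalanine",other,C9H10O7NS,276.0185,276.0184,259;231;215;196;179;150;135,TRUE,TRUE
79,"5-Hydroxybenzofuran-2(3H)-one",other,C8H6O3,149.0237,149.0238,121.02;67.01;65.00,TRUE,FALSE
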