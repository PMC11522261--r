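"original_shape_MajorAxisLength","original_firstorder_10Percentile","original_firstorder_90Percentile","original_glcm_JointEntropy","lbp-3D-k_glcm_Imc2","lbp-3D-m1_glrlm_LongRunEmphasis","wavelet-LLH_firstorder_Maximum","wavelet-LLH_glszm_LargeAreaHighGrayLevelEmphasis","spiculated margin","pleural indentation","outcome"
14.669590190591,-549.900486443466,-71.711210219408,8.73059647764446,0.14767851668424,27.6612236913361,829.603734865007,34227.0678418796,0,0,1
17.8522902310973,-522.46789290483,-237.575841132056,9.15941612602518,0.29294311849167,18.451079596615,926.93764114356,28185.7678703259,1,0,1
6.69772071722176,-646.138612583308,-143.640872031203,8.98058317289979,0.0273952728204709,20.9940072078398,183.108940477327,2609.0136795327,0,0,0
10.6871808556228,-666.981901294793,-23.5651041424025,8.77091448900245,0.11260590260197,27.5796993477589,537.471071259914,44652.0605856834,0,1,1
11.0026753673454,-544.454936437223,-106.535903010059,8.95572703344176,0.0912133241956465,84.9590530490637,852.745568058571,20214.0986074919,1,1,1
9.64300975277918,-948.870954698068,-338.517387906281,8.96144842395676,0.0170318831909132,14.8992838707639,242.840333453336,5278.97656944438,0,0,0
10.6755079533549,-686.290490921745,-18.1066775917094,9.54568043202556,0.20993405322019,34.6240053576481,549.809835058482,163095.796270401,1,0,1
5.33132727830167,-853.599835359417,-366.525067013138,8.90869541484308,0.186159141790443,14.2290415661526,288.597848238093,7551.14122218252,0,0,0
6.93588972211774,-865.56284149413,-568.96351247294,8.80140066616564,0.398626267700852,19.7243724636771,410.447951312757,15407.8960050391,0,0,0
14.7143821768978,-596.026513241852,-77.2675569704011,8.70509859560846,0.365717136188015,34.4722067058281,479.285945142873,52977.6100410102,1,0,1
8.13818560341413,-737.340153977972,-435.085196411146,9.38071815441222,0.0314175946112519,16.9324200962563,296.051160544537,6261.91570655834,0,0,1
7.91326953953276,-639.716302840353,-92.2154152701586,9.31606464688941,0.129575880364803,32.9789555177898,484.483166450455,81180.5785189032,0,1,1
10.9180704345031,-516.602044073053,-32.726440895174,9.23979810312181,0.213183301805338,28.4064704785128,826.848835640457,188497.438418002,1,1,1
10.7017111485858,-839.937530978423,-170.039475906098,8.64559655810741,0.0618942661423211,19.361155560134,241.612619061605,3335.19806105629,0,1,0
12.0962686170399,-910.510914886122,-489.09380892117,8.16255199717776,0.0852516956312873,11.8155514639627,246.86864905703,14180.6005897801,0,0,0
10.3678419906771,-552.390017152241,75.3813948066216,9.47539860411817,0.223976152207213,21.4955466009884,714.682712542688,48987.2739194399,0,1,1
10.7332762888478,-689.253249380534,-69.6227820371888,9.10228706941406,0.214936042609354,35.1399379111469,386.916086635473,110192.415780823,1,1,1
6.26133141077135,-601.148861210662,-224.224085195357,8.61775948215064,0.0943046221810011,29.2746232013355,294.555712225382,7152.3890830931,1,0,0
9.34255460475129,-807.459082287468,-241.890714756403,9.12000584785702,0.108086754397239,20.1972560607641,149.244709528584,20776.938502959,0,0,1
7.66422291005382,-687.878732825757,-271.868275569971,9.06979789972871,0.0577350508013116,24.000528231962,507.252431309015,1571.71710003088,0,1,1
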