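"n","p0.5","p0.25","p0.15","p0.1","p0.05","p0.025","p0.01","p0.005","p0.001"
4,0.257530622337235,0.292648479030558,0.320288120488757,0.344446283471712,0.374649297991186,0.395133869947239,0.413853783594579,0.422738060495895,0.433379795033087
5,0.234143188054072,0.279527966981932,0.303969493856146,0.320239111009322,0.343844013384829,0.369469111101627,0.398642620825268,0.414405795078857,0.438319526245302
6,0.219265745565715,0.258525561116971,0.280832096106345,0.297175843672379,0.324057529652451,0.344999569065818,0.372556132101744,0.390213959131698,0.420624162634679
7,0.205873432934109,0.241904797304035,0.263481315394719,0.279254593279932,0.303002538916193,0.32414319362427,0.350724624023629,0.367573218910327,0.403709422125734
8,0.19494096406955,0.229533397537664,0.250559178680986,0.265874898570748,0.288091826351707,0.309091772385132,0.332804597736893,0.350545362698321,0.383798512895654
9,0.184618990007204,0.217601470094501,0.237650266909098,0.251730985544299,0.272603353008442,0.293791856928071,0.316349770309697,0.33109167092212,0.362273457406244
10,0.177433518987352,0.209413455871503,0.228336365007426,0.241611590304099,0.262444651141692,0.281232888271524,0.305339911544312,0.321841023847886,0.358856129056987
12,0.163107935259867,0.192396253337432,0.210136677639591,0.22300969436706,0.242709105301057,0.260486672774469,0.281038511676833,0.294250436539217,0.320870092344585
15,0.147403695003421,0.174438075501976,0.190708493074017,0.202048078288707,0.220168181045962,0.236564245578952,0.253575768869997,0.266941836560267,0.296464396116959
20,0.129465846097151,0.152133478567397,0.165807679654845,0.175611247118147,0.191127148702149,0.205128354211841,0.221013178944825,0.233161881941955,0.261715536350371
25,0.11618282704184,0.137345817221836,0.149699503448673,0.158294995986876,0.171952992897199,0.183797906869743,0.199410938215091,0.209572451859806,0.230820145678843
30,0.106949546741768,0.126346078202097,0.137819888451814,0.146114999081914,0.159364587994892,0.170779071687091,0.184466045230549,0.19425187926094,0.213409802016799
40,0.0935024711661528,0.109389752654293,0.119861497120932,0.126880150110789,0.138175518824314,0.149348054424106,0.161833905078824,0.169588284333666,0.188578210546603
50,0.0837576094809234,0.098557384482426,0.107515682075284,0.114061828988909,0.124080919220092,0.133227109867636,0.145089966550864,0.154024751267785,0.171341783487944
75,0.0691339983526794,0.0813841816225499,0.088374990468556,0.0935708846848015,0.101965914183881,0.110209105645692,0.120330782598751,0.126814480724472,0.141029878564235
100,0.0599699144028154,0.0706462342703776,0.0772041915642082,0.0822146321510195,0.089446006707872,0.0960811852575814,0.103379120866327,0.109431140427402,0.122060563905985
150,0.0492528460769197,0.0579374786206649,0.063173623420459,0.0671826390127257,0.0731106500507785,0.0786408785067637,0.0858914428020187,0.0910812018547652,0.0990060166990814
200,0.0428469164429047,0.0503301061421296,0.0547688675890772,0.0582106493872257,0.0633662144021081,0.0680058336770362,0.0738549975950922,0.0780211797741307,0.0874561936013065
300,0.0351429024099055,0.0412485830908865,0.0449370667124867,0.0475140491475084,0.0519074633646838,0.0557847346392571,0.0608686548254314,0.0635049703958141,0.0699962837601725
500,0.0273268792538925,0.032149542305451,0.0350334204595957,0.0370969573351417,0.0402534227565318,0.0433174469914746,0.0468191157141988,0.0494877386799609,0.0544918235602102
1000,0.0193788227625338,0.0227963165221103,0.0247957172261671,0.0262910131942273,0.0285870996406361,0.0306014595279499,0.033068887028272,0.0346124319851837,0.0397486498066908
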