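>mtsD_1
IGDWVLYKIFGITIQFTWVCPRSVDVDYKAVWPSHQVHVMATSEYVHHHPKTQLVKDVDRPLDYKQCNCA
IKSFNVRCGWLLEAWNMFPQPPLVYQKPEDFWQFPFETSHAHPAKGFSSQCYIKRQMHREWSIHPTDIEH
PSFFARRDTWDHHYAHVMMWWTWAIVWWMMRVEELLLAFDERKAKVTFWYVAGKMVLPVFAKSWGIHGYA
FERHAIHWMQWHNCPVKLYKYWTHYCYSVINQHISEIQVSHPWMLMTPMSEDVPYNVKGRVAEFRLQQAM
PGIKDLWHWQMQCNAQWCDMHEMTHRGAKFFHWAHRGNLNWFITDGNMQQSCFTHTDYNFWCAVFTWMVC
DRTTKVNVYGAMEYQTEGWWYVSWQWQCYNMVYQRWCSWKRNCLWQAYEEASRHVFVGWLAMFNFWPHGM
SQPQTQMNMVNQPAVNQMPSKHSMNVGNCHSQYFIVKGFGQADYCESAHFHHAQSCPDFQGSLHRLKRSY
PTEVNEELKMAVMKFETHFAGMCVFRNSYADSAYMPSQHEKMLERTDEHNYDWSCTWNGPLYDMESIRSH
WFDFQMWCYGRREAPAFGTDRQFSITASPARHRSVIYIFARGQKHESYIDPGLFHVRQPYNHDQCFSSVL
CARPFYFMTVKKPINLCTPLDMYDEFEFGQEEQYAITGTHLEDRKKHQYEGHHDRTIDAM
>mtsF_1
IMDWVLYKIYGITVDCTWFCPKSVDVDYKATWPNHQLHVMATSEYVRHHPHTLFVENVDRPISFKQWNCH
IKSPNVHDGYLIQIWNMFPQPPLSYQEPVNFYQFPQMTSHQGPAKAFSITCYIRWQMRREWPINECYIEH
GSFWARGETWEHHYAHVFVWATWKIVWWYIKVEECLLGMDEQRAKLNVWHCAGHAVLDIWAKSFGMHGFG
IEAHAIHPMRWHIIPIKLFKWWTHYIMSKINQEISEIQCSHPCLLDTPLSEDVPWNVKTRVAEFRLQQAM
PGIKCLWRWQMQCDAQMCQMHSMSHRGAKFLHWAHRAWLGWFIGDSNMQENTFCYTGFNFFNAIFTWMCC
ERTRKVWAYKVMEYSTEGWWFWMWQWQCFNMMLQKVNSSKRNCLWQAWSKEERYVFVAQIAANHFWPNGM
SQPDSPMNMANDPACSQMEFIHCMNVENCNSQYTILKGDGQANYSEYAYFPHANICKMFQGSFHRVKRSH
PTNVCEDLKATVWRFGTESSPMYIFINSPADSSQMPSQNEKLLERKDENGYEWSCTWNGQLYDMESIWSS
WFDKDMYCYGDHEGPAFGTDRQFSITGSPACHRDVIYIFSRGYKHESWIDKGLFPVRQPYNKRDAFRSVL
CAMYYVKMCVKKPINLCTPWSMWDEYEYGKEEQYAITGTHLRPCKVHWYEGHHDMTIPAM
>mtsH_1
IGDCVVFNIYGITVDWTWVCLKSVDTDYKATGPRHQLHVMATSESVRHHWKTLLVEDVDRPLDFANWNCA
MKSPNVCDGWLIEYWNMYPMPPLSYQKPGNFYQFGQNTPYAYVAKGHGINCHIKVQWRRELSINETDIEH
GSFWSRQQTWTYKYANVYMWAAWKIVWQFMKVKECLLAMDEQRAQCTWWHIAGHAVLQIFAKSWGIHGFG
VERHLIHWKKWRNIPVKLFKYWTHYCYSKINQHITEIQCSHPCMLTYPLSTDLGYNVRNRVAEFRLQQSM
PAIKDIWRWQMQCNAQVMNMHSMSHRGAKFKHWVHRGHLNWFIGDSTMQENCFHHTGFNFWCAVFAGLVC
HRTRKVWAYGVMEYSQRWWWYVNWQWQNLNMMFEKFCSWQRSCLWQKYPQEERYTFVGYLIMTHFWPHGT
SQPDSPYNLVNDPPCRQMEFSHSMNVGNCHSQYFIVKGDGQANYCETAYFEHAQSKPEYQGSLHRVKRDG
KTNVNEDLKMAIWDFDTHSNPACVFCNSYADSSQMPSQNEKALHRKDEGNYDWSSQYNHGLYDMESIRSS
WFNEDMWFYGEREAPWVGTDRMFSITGSMAQHRSVIYIFARAFKHESWIDPGMFPVRQPYNHTQCFTSVL
CPKQFVYMCVKDPINLCTPLDMWDEFKHGEEEQYNITSTHVNDCKKHVYEGHHDMWIDAL
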