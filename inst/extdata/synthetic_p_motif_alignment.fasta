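>motif_1
GVNATTEGDGLCKACWYKEASILFQHMCERGYFFD
>motif_2
RVGSSTFIDDQLKKWREDWAHVLTVFMIHFGILDN
>motif_3
QVSISTENSNSSPQGYTLAALENGMAMGWMGIFRN
>motif_4
VVNTVTYLILDEKFGRHGEAPRFTRCMYKLGECVD
>motif_5
FVYYTTLMMYACKAQWLVEALYAMYPMGWDGMFYD
>motif_6
LVRYATLSGLIQKDFKADGNVIAHQWMKFEGSHAD
>motif_7
AVKHATVLVGVMKVARNETATVTIRNMMIIGICEN
>motif_8
VVTYSTINYLIWKHGKTDYAHISWLMMRMTGIPKN
>motif_9
KVCTTTHIMSREKDGIEDMALFLFIVMQYFGVDPD
>motif_10
VVKFLTFCKMLTKQGRVKHARERNEYMHVMGSKSN
>motif_11
VWIWNTFICETDKLNKVSLAIHLFMEMDWIGAEND
>motif_12
FVLYLTYPSGWIKKRLKLTALTLGFSMWGRGCQAN
>motif_13
WVKLAFWKNHAAKMGREDQALAEFTTMVTSGHCNN
>motif_14
LVTMMTIILWHQKNSTFMLAMEPRRPMMCGGISLD
>motif_15
MVYMTTPIYVLAKMKTQIMAQEGFDCMNAGGQESS
>motif_16
FVMSTTFMADSNLWVMVTVAGWLTLEMAQCFVRRD
>motif_17
SVTYTTHPQHFIKTHSGKCANEIFRLTDGKGILPS
>motif_18
TVTNTTHNFYEMKNSLNDLALHIFPLMIEVGCSPN
>motif_19
CVMYVTCRQQDYKWLKGLCATKLAHEMYGKGKRAD
>motif_20
MVDSGTFYSFQAKFRSCMSAIYQHDLMAFLGMQNN
>motif_21
GVRVMTIVGDQFKNHGSRPAFEANILMVYTGYRFD
>motif_22
LVGRTQQIRPYPKDTEWTEAMVVAWSMYHFGMKPT
>motif_23
PVTFTTIWEDEWKEWRGIRALELMYPMFSKGFCPT
>motif_24
YVPFSTEDSIVLKLGLSCKAFSLPIMMHKGGWNAS
>motif_25
NVMYSELESHIQKEIGSVQAWRIWACMKMHGSQVN
>motif_26
QVALNTRCSTTNKRVRCFRALAGVIKMDATGNPNT
>motif_27
PVLATTKDEFLMKSYKQHNAMELHAPMVFMGINLD
>motif_28
HVYKLTLIKNFMKAVMFDEALGTHRNMATDGYYPN
>motif_29
CVMYAFRGRGDEKPLGVDHASELMTDMRKFGYTID
>motif_30
QVKHTTYLQGILKAGQMREADKVVRSMGEWGQHHT
>motif_31
NVIHNTLITKDCIACKCNPALYDLTDMEKSGFRPT
>motif_32
FVCKTTRITEHYKAGLENLALNNFEAMWSVGFSCN
>motif_33
CVHKSTCISMHCNHSEGNSAARTFYLMTVPGVYPD
>motif_34
VVTSTTPNPSCIKHDVVDAALEEFSEMPEYGWRIN
>motif_35
AVPLSTFSECDFKHRGHQNAYASYRRMKETGAEVD
>motif_36
NVTYVTKIRMDAKHEVVDFALNVNRLMKMIGFHPD
>motif_37
GVTLLTKRLPRSKEDYVWQAYEELRMMIQPGNVDN
>motif_38
FVWHTTDFVSQVKPADQWPALTYCDLMHEKGIRPN
>motif_39
DVTNNTWICGYYKYYHWGEAIPPLIYMYHEGGHPS
>motif_40
SVTKSTLISGPCKAAYVDIACTWRVRMLMHGFVFN
>motif_41
WVDSNTHGSPAVKSCVCKEALHACAEMKEKGKLVD
>motif_42
EVYYATPRQGIHKAWRQVIAPSGNRFMKPKGTLDN
>motif_43
VVTAGTYLFNTDKARGWDKALQVFNLMKETGIAKD
>motif_44
AVRQTTNCAKWMKVVTVIKALYLKIEMEYKGIHGT
>motif_45
PVTWVTAGSGGCKHMAQAHAFKLAEVMKTIGRMPD
>motif_46
NVQYATDTHHYYKACKFDEALECCSDMMLKGIAND
>motif_47
DVWFTTTESTCFKDEPNNWADVGSHEMNWKGIQLD
>motif_48
VVCENTWVNGKDKLYAVDRALQNKQEMWEWGIWLT
>motif_49
VVQHTTNICPKIKNNEFHCASALHQEMKMMGCADS
>motif_50
TVTKLTCPSELVKDYGQPEAWHLDYYMEENGCTRN
>motif_51
EVRYSTWHFGQIKNTIKWCAWKGNSMMTESGQDHN
>motif_52
TVIPSTVKCIVNKHPFVDQALWLRDIMWHCGSCPS
>motif_53
HVAHNTHITSPYKRIAVQEAMTEQRHMKSGGMCIT
>motif_54
HVKVTTGTTGRMKYNNLSYADKTFLRMHQIGYCPD
>motif_55
NVHYTTYFKHDAKQQCCNPAQEAERRMKCDGPRED
>motif_56
MVTCGTLHMCSQKAVWVIYALLNGSKMPRYGARKN
>motif_57
VVKGSTACRGYFKWGDQSDAICLFHGMKHGGINMN
>motif_58
QVRKGTFYTFVRKEWPIDHAQENFRMMYCHGFPGN
>motif_59
QVGLATEHWAKQKHKQMDLAYECWWEMYANGVRPN
>motif_60
CVQRTELKFDVPHAEDLGEAKHYFQRMKPKGIIFN
>motif_61
IVDGLTLINPHMRAYSVFYAWELFCWMGTKGTNVN
>motif_62
CVEYTTPRDWLCGICHWSIAFMSQSHMMEPGVKQS
>motif_63
SVCYGTNIHLWIKYWTLFVAHRPFMEMLWTGIAWN
>motif_64
NVQVNTDLEVACKPARYMPACECNPEMKEEGAPMS
>motif_65
YVVRSTFTSGHMKDHRQYMAYHLNWPMSFKGINEN
>motif_66
SVSRTTWPIKVSKTMYGDTAQFFLTGMYELGIRKN
>motif_67
MVSFTTSDFFQKKAYVVPVNHALFEDMFCYGDLVN
>motif_68
LVGMTTVMSFDAKLGDGQTAVEIVAEMHENGNRCS
>motif_69
GVCYTTRIIVPCKTHNDEAAHMASKPMPTPGWCYD
>motif_70
LVMGTTNHSGIMKIIRVVEALTNFRMVDEKGILNN
>motif_71
IVETTTPDTGFCKHAVVEYARRLWRCMFYDGIFDN
>motif_72
IVMYTTSSSQIVKFDQKVCALMAFFWMEVNGISPN
>motif_73
PVTMTTGPSKLMKDAHCEYAYMTFAFMCSIGFTDS
>motif_74
IVQGTKQELYESKFMKVLRAILFPQSMKEIGDMPD
>motif_75
MVEGTTVCSSAIKAFHNDKAIHCHWNMVCQGPSLT
>motif_76
KVLYGTCTSGPIKWFSMFDANVLVMEMPNDGHWWD
>motif_77
VVWCNTIDMKFCKTAEVHEARTRKRGMKNKNYICT
>motif_78
MVHKTTCSSKVCKAIKWSTADCHMRIMGECGIMHS
>motif_79
PVEENTHIDTTCKECCVKFARHQWAEMKDKGCSGS
>motif_80
WVTPTTWVQSLCKPGHLHHAWYQVRKMIVEGERGD
>motif_81
VVKFMTKLTTEFKHKDLIRARHLARNMKMSGITID
>motif_82
VVVPATLCRWRCKEHRVIIAARLFNSMTGGGIQLD
>motif_83
VVELSTMIPSLNKAQAIHEAGMRYTHMAEKGNRED
>motif_84
WVPYMTRADDLRKSKDQSEASPLQYRMQELGNWWD
>motif_85
AVTFMTHSSGLEKTMRFVWAIWLLFLMEAVGPLID
>motif_86
IVGLATRLALGFKYGRDNNAEGTQHAMTERGASED
>motif_87
AVQWLTGGSNGPKQRICPCAWVCIAIWLHWGKLVN
>motif_88
VVTLSTEIVALIKAKCDDRAVHDMESMGSGGWEAN
>motif_89
VVIQTTLQCRAVKTGWVEEACELFREMGMFGNFLD
>motif_90
HVMPTTHISCSNKASLVQEANWMFVIMVKSGFWYD
>motif_91
FVGGMTEGSVQIKDGRRKEAGFDPIPMPSSIKQTD
>motif_92
NVPNSKDMQENEKSIPVHEASQHWRNMFKKGEWFN
>motif_93
NVIYTTFCSVQGKTVKVDAAKCAFMCMFEEGNRST
>motif_94
VVHWMTNISFSVKVIHIELAQEKFYAMQNPGTKED
>motif_95
IVSNNTSTPGLGKWGHETNACETVDWMSRMGITPD
>motif_96
RVRINTDQIMLVKHQRVSGALSLQCIMDMYGEMET
>motif_97
AVTHNTFHTCTINAGEVNLACCQQNVMDYLGKRPT
>motif_98
CVRGNTLISCYLKMWLHDCALAWHACMKEGGAMPS
>motif_99
DVKHGTLWKMFGKLWRVCSALMDYRLMCYRGRHCN
>motif_100
HVDDSTTQQVYRKQGPAWIAETRTYEMQSPGSEGD
>motif_101
RVLSVTFMWLGWKPDRWGIAMMPSNWMIMSWFRPD
>motif_102
TVFYSTSCNHLIKNKFEDYAHPDEVSMKPWGRFDD
>motif_103
HVRFTTAFDGLWKSNHHDPALAIFREMKPRGIAWN
>motif_104
VVTHMTATELCRKATIVCTAYCFHYWMKHKGISRD
>motif_105
QVPWTTFDVFICKAPRVALATECQKEMKYEGWFPS
>motif_106
CVGYAVTNCNNPKMEELMHALYHMRCMNEKGIMED
>motif_107
NVGTNTARSKLAKFGLMRSSNEKNREAHGMGRPPT
>motif_108
LVDCSMGHSPRKKSILSYGAAEQFWHMKENGSEPN
>motif_109
KVTDTTDPYENDKTVIVLIAVFKFITMKVYGYTVT
>motif_110
GVMWSTGRCGDTKANMRSRAQTLLFDMKQEGIRPD
>motif_111
VVAKATFILNKNKEHEVAMALDRDILMQGCGWPAD
>motif_112
VVKYSTLPNILCKKVFKPVAWILPWMMRSLGCVLS
>motif_113
SVRMTTLDVKMSKVLRPWKAVEFFFAMHSAGYYPD
>motif_114
VVHWNTHCGRTGKGRGTYEAPWKCFYMKDHGCYQS
>motif_115
YVDQNTCCMRLPKQGAYAHATSGFRTMLPVGFRMS
>motif_116
GCFIATEHFGRQKASQYCRAVWVLRYMSEMGIRKD
>motif_117
QVTLTTCTSGITKRFRPTQACYFNHHMYEKGIRMD
>motif_118
GVIITTANEQDAKYLDCPEALEKCLMMYVEGGRPD
>motif_119
YVTSSTQDSGIIKYTWVVMALELVRAMPSMGWEAD
>motif_120
KVNALTQSGGNVKLNCILAAVWLPRMMIWCGNFCN
>motif_121
CVVHATHYSIAHKRIRPDLASEFPSVMEKVGWGCN
>motif_122
VVNYGTFWSLLDKRARCTPASVLNCEMQRQGPWKN
>motif_123
RVFKTTNICFKAKKWPVSRATLVHKEMENHGDWPD
>motif_124
FVEATTALLWQMKCAGSKTQWEFPDAMKEKGIWMD
>motif_125
DVTMVTCDGIACKVGEIPAAPQKDRTMWYKGHSPD
>motif_126
QVFVSTIEPSQDKRLQVEEAAEAVHYMENLGNDDD
>motif_127
VVCVMTMHNAMMKIKPFDEAWMICFRMHEMGPLYD
>motif_128
LVTLNTAHHWRLKAFSVQPALHQHFEMHEQGIPMT
>motif_129
MVIFNTCAHPATKCYVLDEAHMPAIRMKEFGIAKD
>motif_130
KVRTTTEEVTTMKFKVKEYAGVCYKIMKEVGIRPD
>motif_131
MVKEMTTWMHLCKAGFVDQEIHTGMVMKPRESGQD
>motif_132
QVFLATWQSGRMKTRSKAGANHNDDGMCVMGSRWD
>motif_133
VVNWSTQINGYQKVDADWVALSMFWAMPYLGIQYD
>motif_134
EVMFSTLIASLSKQFIGFAALEYDFHMSGYGIIQS
>motif_135
MVDLSTNEWQNGKFGQDDDAWKWYDRMEEQGGIND
>motif_136
CVEMTTQQKPTDKSGWSWIAWNNLMVMKEKGVRCD
>motif_137
DVEKTTMCDCHCKSHAVMMKICHYKFMWWAGWRDN
>motif_138
EVTYNTPPSSWIKSWLRVAAWLPTECMKYKGEQIS
>motif_139
VVMYSTYRSQLCKKWQGGTAREHFALMVSEGAHND
>motif_140
DVRRSTTRSQLIKMQEPDHADACFGGMQKKGKIRS
>motif_141
RVDAVTGDGNCPKFCQDTGALMTEFGMWMRNIIWD
>motif_142
RVQFATWPSLSTKHDYKTEAVNIWRIMDKKGQDFD
>motif_143
VVMQGTERQALCKGSHVVKAVYQHREMKCQGRWHN
>motif_144
WVFLNALIWFLCKCVINYEALMYIAAMQSLGTSPD
>motif_145
RVYYVTRIPRLKKQERCVPAMAASRSMTCSGAWND
>motif_146
VVPNNTLLVMTFKCASEKPASHWQLEMFKKGNMIS
>motif_147
LVKYNTPQAHSYKKKNYDFAPTSKNSMLEKGMWIS
>motif_148
VVWPNTLASYREKSHIKINALEHFREMPRSGIPQT
>motif_149
LVVMTTANMWNYKGTAFSLALMWYQCMKPKCFSGD
>motif_150
VVEITTDTTSQDKIMWHKEAVKEWHHMTWYGKGPD
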