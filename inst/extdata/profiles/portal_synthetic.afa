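>portal_01
VADTSQ-VQCSQQEVGSFNCNQLFK-E-GGMCTWGAAVLINLSDPKSNANHFIFFGITC-TPELFWY-NGFWHS-FEMRMEISLYLTLEGVCASYKLVAGSED-FTLRRQVCAKLFELCSIVYP-WCRYPDVKWYMADSWVLTWMCNCYSDPWQLTMLPC
>portal_02
VADVSQPVQCCQDEVMT-GCNYLFK-E-GGMFTDGAAVSYVLSDVKANAQSFICTGITCR-PESFWFPFKFTHS-FEMMMEIIYLLDLRGVCASYQLVFGSQFKFTWVFQFCFCLMELLSIVYPFWCRYPDFKIHLAVSWVLTIMCWIQSEKWQWCMEGA
>portal_03
VADVSQ-VQCWQQEVWSDNCNQWFKEEEGGTFTKGAAVLQNLSDHKGNASQFIITGITCRTPEGFWVPNGFTHS-FEMAMSIIDQLELCGVCASYKLVVGSMT-HTAVHQSCMDWMELCSIVYPFWSSYPDTKAYYANSWVLTGMCKINSDFWQSCMEGC
>portal_04
VADIVQPVQCCQIEVMH-NCNQLFW-E-GGMFTHGAAVHILLSDNKLNAEIFIITGITTR-PERFWFPDGFGPYYFEMVMAICTKLHLEGVCASYKLVLGSQW-CTLVRQGCMDGMELDSIVYP-WCSYPDTKWGMAMSWVLTFMCCFASDPMQACMNGM
>portal_05
YADVTQ-VQCWQPEVASTWCNQLFKEE-GGMATSGAAVTINLSDTKNNATSFERTGIACR-SEWFWGPGYHWKS-FEMMMEIILELTLCGVCASYNLVFGSVW-PTLWRQSWRDLMELLSIVYP-WCSYPDATWYMADSWVLTQMCEIDSDPWQRCMESL
>portal_06
VADPHQ-VQCSQEEVMS-NCNRLFKEEEGGALTKGAAVLMMLSDYKCNAHSKIIEGITMRTAEYFWHPPGLQHS-FEMMMEINCQLTLEGVCASYALVFGSQMKITLVRQSAQDQGELLSMVYP-WCSYPDQRIWMAPSWVLTGMCNQNSYPWRPKMEGR
>portal_07
TADKCHPVQCAQPEVMWNLQNSLFM-EEGGMATVGAAVDQNLSDIKTNAMSFNINGISDR-PEYFWVPQSFWQSYFEMLMYIIPQLNLEGVCASYKLVFGSQW-ITLVRQLWMDLMELHSIVYP-WCSYPDTKIMMADSWVLTFMCNINSDPWNRPMEEY
>portal_08
DADHSQPVQCDQQEVMM-NCNEVFF-E-GGPFTKGAAVLINLSDVKANAESFPVTGITC-TPECFWF-NGKWHDYFEMRMEITRVLHLAGVCASYKLVFGSQWKFTLGRQSCHDNLELLSWVYPFWMSYPDTKWYRALSWVLTGMCNINSDDWQIVMEGC
>portal_09
VADVCL-VQCRQQEVMSSNCNQRFWEE-GGLFTAGAAVLINWSDDKSNAETKIIPGITC--PEDFWF-GIPWRNYFEMHMQIIRYLDLEGVCASYKLVFGSIWKFTLWRQSHPDLMELLSIVYP-WNPYPDTMATDADSWVLTEMCNRNSGVWIRKMEGC
>portal_10
VADYWCPVQCEQQEVMSTNCNMLFFEEEGGMFTMGAAVIIQLSDVKSNAESFWQDGITE-TPESFWF-NGTEHS-FEMMMTICRTLRLEGVCASYQLVTGSQI-GTKGRQPCMDAPELPSPVYP-WCSYPDGKLYQAKSWVLTGMCNNMSDETNYCMEVC
>portal_11
YADVSCPVQCEQPEVMS-TCNQIFYEEEGGHQTKGAAVLHNLSDVKMNAEEFIITGIAN--FECFWF-HGFEHS-FEMMMMIFDFLTLTGVCASYKLVFGSRW-NTPWRQSWSGLIELDSIVYPFWCSYPDTVWYMAMSWVLTSMCKICSFPWLRRMHGY
>portal_12
VADVSQPVQCSQQEVMS-DCNQCFY-EEGGMFTGGAAVTKNMSDVKSNAEQTRITGICC--DEYFWK-NGFEKS-FEMMMEIKLDLTLEGVCASYTLVFGSYK-CTLVRQCQHVTCELESIVYPFWMPYPDSVSTTADSWVLTVMCMENSDPEQPCMVGK
>portal_13
RADVSN-VQCSQQEVMS-NCNQYFLEE-GGMGTKGAAVLILTSDVKSNAEVFSKTGIQC--GEYFWF-AGDYHYYFEMKMEIILRLFLEGVCASYTLVFGSDQKITDVVQSCKEQWELWSIVYP-WQSYPDKKWYMADSWVLTGMCNINSHEWCWVMKGC
>portal_14
VADTLQPVQCSQFEVFSNNCNDLFE-E-GGLFTKGAAVRIALSDYKGNAEKWIIYGITC--QEQFWF-NWFWYMYFEMMMNIQLRLTLKGVCASYKLVRGSQWKFTGVRQYCFVEMELHSSVYP-WCSYPDTWWIMADSWVLTRMCYINSAPRYRCMEVC
>portal_15
VADVSQ-VQCEQQEVMSKSCNQLFAEE-GGTFTKGAAVLVMLSDVKNNAHSFNIIGIAI--PETFWF-NGFRVI-FEMMMYIILRLELEGVCASYKLVLGSQW-FTNGTQSCMDYTELNSIVYP-WVIYPDTWWMMARSWVLTGMCRRNSDPNERCMEGP
>portal_16
VADSNQ-VQCRQMEVMY-LCNQHFK-E-GGMGTKGAAVPANLSDVKSNAWSFISTGITM--PEYFWTPSAFWES-FEMWMFIDLLLTLEGVCASYILVFGSYWKDTLVNQVAQDDMELLSIVYP-WCCYPDTKWPMALSWVLTIMCYNCSIPRQNCMYIE
>portal_17
VADHYF-VQCSQAEVPQ-NGNQLFC-EEGGIFTKGAAVLIDLSDVKSNANNFIFTGITCRTPELFWFPFCFWHSYFEMMMYIILYLHLEGVCASYKLVMGSWWKFTLVRQTYQDVIELLSIVYPFWCSYPDLWWYMAVSWVLTAMCYINSDPWHRLMEGC
>portal_18
VADGWQ-VQCAQQEVMSNNTNQLFLEE-GGMFTKGAAVNGNLSDLKSNAESRIITGIQF--SETFWT-NGDWHG-FEMWMNIILRLILEGVCASYDLVIGSAD-NTLSNQSCMDLMELQSIVYPFWCKYPDTEWMSASSWVLTCMCKRMSCYWQMCMEGW
>portal_19
VADPIQ-VQCSQQEVMS-FVNQLFK-E-GGSFTRGAAVLINYSDVKSNAEGFGYHGITE-TPEYFWS-NGFTTS-FEMMMEIIQRLTLMGVCASYKLVHGSFDKFTLWWQSCMQAHELGSFVYP-WYKYPDNKNYMANSWVLTGMCNINSDCWQRPMEIM
>portal_20
VADVKQPVQCNQMEVMP-NCNQLFK-E-GGMFTNGAAVKINLSDVKQNAEDFIKTGIEER-QEYFWFPNGQWQSYFEMMMQIILRLTLWGVCASYKLVFGSPWKRTEVRQSCYMLEELASIVYPFWWHYPDGCWYMADSWVLTGMCNINSDAAQMCMPVC
>portal_21
EADVSG-VQCLQLEVMS-NCNDQFVEEEGGMFTKGAAVLIKASDPKNNARGFKITGITC--PEYFWN-NEPAHS-FEMMMCIILRLFLEGVCASYCLVGGSNI-ITLIRQFWCEAMELLSPVYP-WMQYPDKKLYMADSWVLTGMCAEPSDWWQRCMEGC
>portal_22
VADEIQPVQCSQGEVGT-NINQQFK-E-GGMFTKGAAVNANPSDVKKNAPNFLFTGIQC--PEAFWAPNGYMVSYFEMMMAIIFPLTLNGVCASYKLVSGSQW-KTTFLQRCLHSMELLSIVYP-WHSYPDKMCYMAMSWVLTPMCNYNSDWYTRIMEMC
>portal_23
VADVKQ-VQCLQWEVYS-NCNIDFI-EEGGGATKGAAVSINASDVKSNAESFHIIGIVYRTPEWFWR-NEFEHQYFEMMMEIWLRLTLSGVCASYKLVHGSQW-FTLVFQSCCDEMELCSMVYPFWCSYPDEKWPMADSWVLTDMCQNDSLPWSWDMEYC
>portal_24
QADHSQ-VQCSQWEVQS-LYNWKFEEE-GGWPTLGAAVLILSSDVKSNASPFIATGITHRTPEYFWF-ETQGHQ-FEMTMMIINRLTLEGVCASYFLVFGSKT-FTLVRQSCMDIMELLSWVYP-WCGYPDTKWQMADSWVLTGMCNIASPHWMRCMNGC
>portal_25
TADLFQ-VQCGQQEVTSSASNQWFH-E-GGMFTTGAAVWIILSDVKGNAPSFIITGITCR-GEYFWAPKNTWLS-FEMMMLIILRLLLEGVCASYKLVFGSQCKGTLVKQTCMDHMELGSTVYP-WDVYPDMKWLDADSWVLTGMCNINSRTWQRTMWTC
>portal_26
VADLMQ-VQCSQQEVMSVNRNQKFH-EEGGDFTKGAAVTINLSDPKRNARSIGFCGITAR-PEAFWF-NGFYHS-FEMTMGIIIVLTLEGVCASYPLVFGSQWKHTFVQQSCMDLMELLSIVYPFWCSYPDTKWYMAKSWVLTEMCWIQSDLGARSMWGC
>portal_27
WADAHGPVQCSQQEVWS-NCNQHFM-E-GGMFTKGAAVLICASDVKGNAQSFGIPGITC-TPEYFWF-HGRWDS-FEMMMKIFLRLILEGVCASYELVFGSQW-FTLTRQSCMDWFELMSIVYP-WTSYPDQQHALADSWVLTTMCNIASDPWQRKMSGC
>portal_28
WADVSG-VQCSQSEVAY-NSNPWFKEEEGGMFTKGAAVAIHTSDVKCNAEPFILTGITC-TPERFWT-NQIWHKYFEMMMEIPWSLTLEGVCASYKLVFGSDW-FTKVCQSHMDKMELRSQVYP-WFSYPDMKWYMADSWVLTPMCQIFSFPWHGCMVHC
>portal_29
VADGEQPVQCYQQEVKSNNINQLFM-E-GGMFTKGAAVQGTLSDEKHNACSFIMHGITM--IEYFWHPERVWHDYFEMMMEIIYRLHLEGVCASYKLVAGSQM-FTLKRQSCMDLMELPSIVYPFWTSYPDTQNYEADSWVLTPMCNGTSEPWQRCMEGC
>portal_30
KADTYP-VQCSQNEVMS-NMNNPFK-EEGGMNTHGAAVLIELSDVKSNAEQFIKTGITC-TPEYFWP-NGFEHS-FEMRMDIILRLFLCGVCASYFLVPGSAY-ETECDQSMADLPELHSIVYPFWCSYPDTKWLMADSWVLTNMCSINSTPYQLAMETC
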