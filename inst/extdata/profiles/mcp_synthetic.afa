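>mcp_01
GIYHRLTPAYNQDVMVMNCWMGEMMWSFPSLHPDEKVFIRNELVNCPLLEHANVNNIAKTMFYSHWHNWHYPLNW-I-ATQTTAMQ-NSWGLRCELP-IQKYMGLWLYYSWSTY-DQYDFNEMQN-CNSAQCMDPECRLNRPWSWEHYDT
>mcp_02
GIRHRLTKPYQQIRIYMRCWMWECMWSFKSIHYAEDVMIMNECTACPILDRANVPCEAFTMFYSNLFGGHTPFNI-CEACTTTACQ-NYKGWKEWLC-IVKAMGLR-NYSWSTY-DQYKFNEMQLGA-CAQCMTPEGRLNRPYSWEHEDI
>mcp_03
GIRHRLVAP-LQFNHVMSCWMWDNFWSFHSIHYDEGVMIENEEVNCPVLDRANCWRWFDTMFYRHHCYGHPPQNW-LEACTTTAQQ-NEKLWPHELRAIQKAMGIN-NYPWSTYADQYMINEMQL-C-HAQCYGPEVRLNRPWSFEPWKP
>mcp_04
GIYKRLGKPYQQQCLKMQCWMWERKWSFPTNHYFEAVMIENEEWNCPILERANNTCWRSTMFYSDWTMGHIWLEW-C-ACTTTACQ-NPKVMYMWLP-IQKAMGLKLMYSRSTYADQYTANEMQLGC-SAQCLGPECRLNRPWSWEHCDP
>mcp_05
GIYIRLMKPYQQKQLYMQCHMWECKTSFPSIHYDEQVMIENEATNCPELDRANVPHWAKTMFYNHWCKGHTHLEVDQEACITDAVQ-NVKLWYCMLCAILKAMGCE-NYSWSTY-DQYDGNEMQL-IRSAQCMSPECRLNRPISWEMYIP
>mcp_06
GIYVRLTGS-QQDCLYMLCWMGWIGWSFKSGHYDEAVMIYNEHTNCPFLGMANWLCMATTMFYSKWCRGHTPLNWDC-ANGTNACQSNYKGWYCWLK-IQKKMGLILMYSNSTY-DQYMFNEMQE-CVQAQCKWPECRLNRPWSRFHYAP
>mcp_07
GIVHRLLNPYPQLCLYMECWMSNCMWSFMVKHEDEAVMICNEETNCPELAAANPMCWGVTMFYSGWHNTHTPLELLG-ALTTTASQSNYKGWYNWLPTIQKNMGKK-KYSYSTY-DQYDFNEMQPGC-AAQCMVPEDRLNRPHSWELYEP
>mcp_08
GIYGRLTKP-QQDCLYMECWMWDCLKSFISIHYDEAVCITNETYNCPELDPANRVCAAKPMFYSVQHTGHTPENA-CEAQHTTACQSNDKGFYCWLV-IDKKMGSILNYSVSTY-DQYDFNEMQLGCDSAQCMGPESRLNRPTSGEHYYP
>mcp_09
GIYHRLTKDYQQDCLYMECWMWWCMWSFIYIHYDELVMIENEETRCPGLDAANVRMWIATMFYNHWHNHHTMLNW-CEATTTCACQ-NWKCWDCWLP-ICKRMGLF-NYSWSTY-DQYDFNEMQE-C-SAQCMQPEVRLNRPWSGEIYAP
>mcp_10
GIYVRLTKD-QQWDLGMECWMNVLVWSFTFEHYDEAVMINNECTNCPELDRANDPCWQKTMFYDHVVLGHDPLNWDCEAGTTVACQDNYKGIYRWLP-ICKAMGLELNYSWSTY-DQYKDNEMQI-C-YAQCYPPECRLNRPNSWEQYDP
>mcp_11
GIYRRLTFEYQQCILYMECCMQENMLSFPSRHYSEAVMIVNESTLCPELDRANVPAWAKTMFYSLWHNLHWNNNHDM-ACTTTAIQ-NDSGWHWWLEAIIKWMGHM-NYGVSTY-DQYGFNEMQLTHVPAQCMDPECRLNRPWSWEHWDP
>mcp_12
GISCRLSKP-SQDCLEMQCWMWEKANSFPPMHCAEAVKIENETTTCPELDRANVPHWAFTMFYSANKNGHFTLNT-C-ACWTAAGQSNYDGWWCWLP-IQKNMGKI-NYSWSTY-DQYSRNEMQK-CVPAQCMGPEHRLNRPLSWAHFYA
>mcp_13
GIHHRLTKI-QQDGFYMWCWMWECFRSFPMDHYDEWVMILNEETNCPELDLANEAPWKVTMFYNCDDIGHTPWFW-YEAENTTACQANCAGWYCWLW-IRKAMGLI-CYSWSTY-DQYDDNEMQKGS-KAQCPTPEKRLNRPRSWEHADH
>mcp_14
GIYRRLTLDYEQCCCRMGCWMWLFTVSFPMIHFDEAVMIANEETNCPILDRANVPCWPIAMFYNWWHNGHTTLGW-C-AHETTACQ-NYKGNYTILVAIFKPMGGSLNYFWSTYADQYEFNEMQC-G-GAQCIGPENRLNRPWSWLIYDP
>mcp_15
GISHRLTKD-KQTDLYMECWMCSGMWSFPSSHRLEAVMIGNEEANCPELRRANHILTFKYMFYHHYHSWHTPLMWDC-AIHTSAFQ-NFKGHCFWLWAIDKAMGLKLNYSWSTYADQYDFNEMQVEHVSAQCNQPEVRLNRPWSICHYLP
>mcp_16
GIHTRLKNK-QQHCLYMECWMWHCMWSFPHNHYHEAVMICNEEFNCPQLDRANVEAWACTMFYSHWKNGHRCLFP-C-AITTTACQANYKDWYQWLPAIQKNMGLQ-NYYYSTYADQYDINEMQL-C-PAQCMVPEFRLNRPQSSEHYFA
>mcp_17
GINWRLTKD-QQDENRMMCFMMECMWSFRSFHHDEAVMIENEITICPELDRANFPKWMPNMFYSCWHNGHAPCNW-C-APTTDACQ-NNLQMYCGLP-ILKQMGLI-NYSWSTYADQYDGNEMQLGN-SAQCMGPECRLNRPCSWVNWDP
>mcp_18
GIMHRLTSP-WQDRLYMECWMDECFWSFDYIHHDEGVMIENEEYWCPELDDANVPPWAKTMFYSHWRNQHFAPNCIC-AFWTSACQ-NYKQWYGWLI-IVKYMGLI-CYSYSTYADQYDPNEMQL-C-SAQCMYPEDRLNRPWSVETYDN
>mcp_19
GIKHRLQKY-QQGPLYMDCWMLECMCSFPPWHYDEKVMIQNEETNCPELDRANVPFWAATMFYSEWSNGHTILAIDP-ADTTTACQSNVKPWYQWLP-IQKAMGLS-DYSWSTYADQYDPNEMQP-CVFAQCMGPESRLNRPNSWERYRP
>mcp_20
GIVGRLAKY-QQKKLYMVCWMWETMWSFPSIHAPEAVCIMNEMTACPELAVANVPCWTVPMFYHIWHNPHTDLNGNLEACMTLACQSNYVGEYCQLAAIQKAMGLILTYQWSTYADQYYFNEMQL-CVKAQCQDPEARLNRPFSIGHYDG
>mcp_21
GIYIRLTKQ-QQDWYIMQCWMWFCMRSFQSSHYDEAVQIGNEETICPELPRANIPMMAKTMFYTRGHLGHTWLDW-M-ACTTKACQ-NWKGNYFGLPSIWKAMGHILNYRWSTY-DQYDVNEMQE-R-PAQCMRPEFRLNRPWSAECYDP
>mcp_22
GIYHRLMKPYVQNAPYMECYMWECMWSFPSEHYTEAVMIENECTNCPKLDRANYMLWHATMFYSDTHCMHAPLNW-IEACTTNAEQ-NRKGWLAWLPVIQKAMGLALNYRWSTY-DQYHFNEMQA-C-SAQCMNPEQRLNRPPSWEYPDP
>mcp_23
GIDDRLTFTYFQDHLQMECQMWHKMHSFPSHHYDETVMIMNEETRCPNLDRANYPPFVRTMFYRHWHYDHTVLNW-LEARTTSACQ-NLCGAYYWLT-IEKAMGCY-NYSWSTY-DQYDKNEMQL-H-PAQCMGPECRLNRPGSPEHFDP
>mcp_24
GIYHRLTPPYQQACLQMFCYMWGWMWSFQVIHLQEAVMIENEQTVCPELCRANWTCVAHTMFYHIWHCGHINDQWDC-ASTTTACQHNYKLHHCWLW-IQKAMGSI-NYSWSTY-DQYDWNEMQL-H-DAQCEGPENRLNRPLSNEDYDP
>mcp_25
GIAHRLTYP-QQCCLYMHCPMWEPMWSFPPSHYDEAVMIHNEQPNCPELDQANSPDWRQTMFYSNWELTHTPLLW-LEAQTTTALQ-NYKEHNCDLA-IHKGMGHI-NYSWSTYADQYDENEMQLGCVSAQCMGPELRLNRPWSWEPYCP
>mcp_26
GIYERLTKMYQQDCLYMKCWMWECMGSFPSIHYFEAVMIENEETNCPALDRANVPGWAPPMFYNHWSNMHYPLNW-YEAISTWACQ-NTKNTWCWLPAIQKAMGLILNYSNSTY-DQYDVNEMQGDCVSAQCGGPEERLNRPKSWEHYIP
>mcp_27
GIDKRLQKP-QQYCKKMCCKMIDCMWSFPSWHYDEAVMIENEENNCPCLDCANVPTWAKTMFYSGNQIGHTVMNWWE-ACRTTAVQSNCKGIYTNLC-IQKAMGLILWYSWSTYADQYSFNEMQL-C-NAQCSFPECRLNRPSSGVYYDP
>mcp_28
GICHRLTKP-IQDCFYMECWMRRGMWSFANAHSIEAVMIENEMFLCPVLHRANVRCLVKTMFYSKWPWGHTPLSWDE-AIATMACQ-NYNHLYVTLPAIPKAMGLT-NYSWSTY-DQYDFNEMQI-I-SAQCTGPEGRLNRPWSLAHYRH
>mcp_29
GIYIRLTKP-QQLGLNMECWMSECMWSFCQYHSDEAVMINNEEIFCPELDRANVPDIHKEMFYAHWHAGHFPLNW-C-ACWTTACQ-NDPGWYCWLV-IWKAMGSI-NYDASTY-DQYGFNEMQEGRIVAQCMGPENRLNRPSSPENYDP
>mcp_30
GIYTRLTKP-HQDCLHMTCWMWECPWSFPSDHYGERVMIWNEETNCPDLERANSPCWFKTMFYSHWTNWHMPLNW-N-ACDTDACQSNYEGWHCDLP-IHKAMGII-NYTWSTYADQYYQNEMQLGD-AAQCMTPEWRLNRPWSAGNYSE
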