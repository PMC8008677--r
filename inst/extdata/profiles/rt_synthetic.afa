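>rt_01
NSTQE-TWGFYEAETECEILCH-QMNPLYLRPLTMAGCNPS-R-KVKTSALFFEHFPEPAGDRYYNPDTNCAYMSAEFGEEPPWPGAPGPMGMQQMIMYGSWVDTYYPYPNNRAVVVNEAPKHQHLR-FDKSRENHARGA
>rt_02
SCTQHETWGFWENCTEREITCH-PMNPLYEDVLTLTGSNPS-RASVKTSLLFQEWFVEVAGPRYYQKDTNCRYMS-EIGEEPRQWVAEQVMIKQQMIRYGDKRDTYPGQPNNRAKFVLEAPKCQHHRESDKSREMHSWWA
>rt_03
SCTQH-TWFFIEAGTECEIPCH-QMNPLYTDPLTYTGMNPSVRAIVKTSMLFFEFFEEARGPRYYQDYTMCMHMS-EKLEEPRQGVAEGDMCIQQMIYYGAAYDTYPGSFNN-NLDVPEAPALQHIIERDKGRECFRDNY
>rt_04
SCTQH-TWDFHESPTECEIVCH-QMNPLYLDPLTLTGSNPSVR-IVITSDRFFEEFVEAAGDRYYSWNTSCRYMSFEFPCEPRAGVAAKSMYKQQDIYYGDYFDTYQGSPNTRTSDVLEQPKCQHRQ-LYKAR-SHRDYA
>rt_05
WCTQEQTWKFQEIETECEIPCHWKMNPLYLTWLALTGINPSVRATVKTSQYFFEHFVDAVGDRYYQEMTQCISMS-EFTEEPRQGDAEGSMSKQQRIYYGDYNDTYNGSPNNRCVDVLEAPKDQHQL-LDKPR-MNRDMA
>rt_06
SCTSH-TWQFIEAETECEIPCH-CMNPLYKQMLRITGENPS-RARVTTSCLFCEGFANAADDRYYDKDTNCTRMSIECKFEPRPGMAVGLMGKQQMIAYGLYLDTYCDSPNA-ARDVLELPGDQHQF-VDKKR-MFSDQV
>rt_07
SLTQPETWGFMEAETELEIPCHDQMNPLYMWPLTLFGSNPSVR-IVKTSRTFFCWFPSAVDDRYYPFFTCQDEMS-EFQQEPRQEVAIGRMSRQQQIYYGGYTDTYWSSPNN-FPRVNEQPVIQHQW-DMKSR-MEFRYA
>rt_08
CCTQH-TWSFIEAETECEIYCHGWMNPLYLDPLAIPGSNPSVR-GVKTSCLFKKHFVEAAGDRYYQTDTLCMSMSGEFTYEPGIKVACKPMNKQQGIHYGTTVDTYQGSPNH-AIDVLEKPKCQHQL-LEKVR-DAVDYR
>rt_09
ICTFH-TWMFGETETEPEIPCH-VMNPLYLDFLILTGSNPS-R-IVKTSQSFFEVFREHWKDRYYRPDTNCRVMS-EFWEEPRWGVACTPMDKQQMIAYGRYRDTYDGQPNN-MVEVLEAPKWQHQL-LEKFR-FHRDSG
>rt_10
SDTGP-TWGFSEARTECEILCHDTMNPLYLDYLTLTGSNPS-R-IVKTSMLFFSHFVEAACERYYFWDTDDRPMS-EFTEEPVILVAEIFMSWQQGIYYGCYGDTYQKGPNN-AVDVLELPPLQHQLELDKAR-TAHDMA
>rt_11
QYTAHETWGFWECETECEIPCHDGMNPLYLDRLKLMGYNPS-R-DVHTSCHFFEPFVEKFRLRYYQVNTFCRYMS-EFAEEPIQGMAELVMPQQQMIYYGDSLDTYRISINNRAVWVLEMPVLQHPPELDKSREMHWDRW
>rt_12
SCTQH-TWEFIEKETECEIYCH-RMNPLYAFHLTLTGSNPS-R-IVKTSCPFFPHFVEARGDRYYQWETKHTYMSGEFTCEPRQIGAMGPMVKQQHIYYGHWWDTYTGTSNC-CVLVLEAPPCQHDLELEKCR-MCRKYS
>rt_13
QCTQSETWYFIEPQTEHEICCH-QMNPLYLMPLWQFGSNPSVRAAVKTSMLFWEHFTEQTGDRYYQTRTNCRYMS-EFTNEPRQGVAEDPMTKQQYIFYGYYLDTYQGSCNTFANDVMEAPTKQHQLEPQKSREDHRVYD
>rt_14
SNTTH-TWGFIEAMTECEISCHYQMNPLYLDPLMLTGSNPS-R-DVQTSMYFFMHFPCEAGDRYYIEETNCTGMSGEVTKEPRQGGAQGPMSKQQHIRYGDRHDTYMNWWNN-ATDVIEAPMCQHQL-LDKKR-MMKDRT
>rt_15
SPTCILTWQFIEHPTEGEIQCH-EMNPLYLDILPLKGKNPS-RAIVRTSDPFKSLFVIEAGDRYYQGYTGCDYMS-ENIYEPRQYTAEGPMLKQQYIYYGDYLDTYQGSPNN-AVYVLEVPMCQHQLELCKSR-MGAIYM
>rt_16
VCTQH-TWGFIEPETEQEISCH-QMNPLYYYPLLLIGSNPS-RAIVKTSMLFKNHFVRCAGRRYYQPDTHEKNMS-EFKNEPVAGVAFGCMSKQQMIYYGDILDTYQVPPNSRALCVLEMPKCQHIA-LDKSR-MAKDYA
>rt_17
SKTSP-TWSFTEHITETEIYCH-QMNPLYLQPLTSTGSNPSVRADVPTSMDFFENFVEAAGDRYYRMDTNCRYMS-EFTEEPRLGKAEAPMYKQQMIYYGDYVDTYEGSPNN-ARDVLEEPKCQHQLELVKSR-EHMLVA
>rt_18
MTTNHETWKFIECETECEIPCH-QMNPLYVYKLTERGSNPSVR-LVKTSMLFPEHFHEAAWLRYYQWVTLCRRMSGEFFEEPRMGSAELRMATQQNIGYGHYVDTYQGSHNNRAVSVLEAPKCQHQLEVDKIR-VGRGYA
>rt_19
SWTPQ-TWGFIELETECEIPCHRFMNPLYLDYLTLEGSNPS-R-IVMTSSLFAYFFVEAPTDRYYKVYTNSRYMS-EFFVEPRRGCAEFPMSWQQVIYYGGYLDTYCGSPNQ-ASDVLEAPFVQHQL-TDKYREMHFDYA
>rt_20
CWTQFPTWGFIEWETEYEIWCH-AMNPLYLDSLTLHGSNPS-R-FVNTSMYFFDGFAEASGDRYYHSDTNCIYMS-EFTHEPNQGCAIQPMSKQQMIYYGNSLDTYQEVKNN-AQFVNEGPKSQHTLELQKSREQHRDYA
>rt_21
YCTQY-TWGFSEAETECEIPCH-RMNPLYLFMLTLGGSNPSVR-WVKTSRLFFCLFVIVCGCRYYQWDTSCWCMSCEFRAEPRQHVAFMPMSKQQHIYYGDEEDTYDGSPNQWLRGVSEWPIQQHDP-LDKSREMCRYPA
>rt_22
SSTRH-TWIFIETNTEDEIPCHDQMNPLYMITLQLSGQNPS-RAIVKTSMEFFEEFVENASTRYYQEVTNCWVMS-EFLEEPRQPVAEGPMSKQQQIYYGNYADTYKDEINM-AVMVGEIPKCQHTL-LGKSREMHRDQA
>rt_23
SCTSE-TWYFPEQETECEIPCHDQMNPLYLDNLTLEGSNPSVR-RVETSMLFFFHFQEAYGDRYYKWDTNCIYMS-EFTTEPRQGPADFPMSKQQMIAYGSMVDTYQGSQNNRAIDVHEAPKCQHQL-LDKGR-EERDDA
>rt_24
IATVMVTWAFIERETECEITCHNGMNPLYLFPLTLTGSNPS-R-IVKTSMLFFKFFVETAGDRYYQWDTNCRGMS-EFTKEPRQKSAWMPMSKQQNIYYGDQLDTYVGSMNNRRVVVYEAPKIQHQA-NCKEREGLEDYQ
>rt_25
SCTQH-TWRFVEQETECEIVCH-PMNPLYLGSLHYCGMNPS-R-IVKTSSSFFQNFREAATHRYYQWDTNYRRMSLEFQEEPRQGTAEGPMMKQQRIGYGAELDTYQEKANN-AIDVLEPPKCQHQQEYQKLREMHGDYA
>rt_26
MWTWS-TWGFREAITELEIPCH-QMNPLYLDPLPMTGTNPS-RAMVKTSMRFEESFVVAHGDRYYQADTNCRDMSEEATEEPRQGVAESEMSRQQMIYYGDYLDTYQHSPNR-RVDVEEAPKCQHQF-LDKSR-MHRSIA
>rt_27
SQTLA-TWGFIEAETECEIPCH-QMNPLYLDDLTLRGSNPSVR-EVKTSMVFFYIFVEYWPARYYPNVTNWTHMSDEFREEPWQGVAEFPMSQQQMIYYGFYSDTYQGSTNV-IVDVSEPPKCQHIC-LDKSR-DHDDNA
>rt_28
SCTTRCTWGFCEAETECEIQCHSQMNPLYLGNLSPTGSNPSVR-IVVTSWPFFHHFVEAHADRYYQEDTNKYMMS-EFYEEPRQFVAEGPMSRQQLIYYGYYRDTYQGKPNN-AVDVLEHPKCQHYL-IWKDR-MHRDYQ
>rt_29
ESTQFHTWGFIEAETECEIPCHDQMNPLYLDHLTMKGPNPS-RAFVITSTRFFEHFEEMAGDRYYQSLTNCRYMSMEFQVEPTQEVANHYMNKQQNIGYGGYLDTYQGPLNR-AVTVLEAPKCQHQL-LDKCR-MFRDQA
>rt_30
SCTQQTTWGFHEAETECEIPCH-QMNPLYLHPLTKTGSNPS-RAIVYTSMLFFEHFVCAKSHRYYQEYTNCRYMS-ECTEEPDQGVAKWIMSKQQMICYGFTLDTYHDSPNNVFVNVLEAPWSQHDFETGKWREWHKVYA
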