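>terl_01
PQHAHNPWENNQHFMQTCWPWEGQ-VPQILGFPTTFPEYTG-DYSNDEHMQCPPWEHVTEQETWITPATVIECCDQMQNNIY-FSGGIEDSRHI-VLPKGTDRFVNVFGSYDATHEVELSENPDEWWDTHDPGKTIGPA-GKQ-SFGRGNTKFSCNLCGSCFLKDTKSNSCTTNRKYN-V
>terl_02
WQHAHHY-HNNQLCTQHCWKRQGQYEPAGLGFFNRFDQYTI-DDSQVKIMEDIRWEGVTEPNTWITPDTFI-CQDQMQDNIY-PSEGIEDSRHI-VLPEGTDRGQNVFGDMDDTHHVELQFNPDEWKDTGIPGLIIGMA-RPQ-SFGRGKSKFSCNEKGSCFCRDTHSASCTTKMKYW-A
>terl_03
GGHPHGGWENNNQFMQQCWHWLGQ-EPMQLGFFDVFMEYTSTDYSNNKHMEQERWESVVEPFTWITP-AII-CCDQMQDNIYRCSVGIEDSRHI-VLPKGTDRIDWVFGSWKETHLHELQFNPFEWVNTDILYLAIGPA-VFQ-SFGRMRAKFSCNEKGSCFCADTKSNSCTVNMKYT-N
>terl_04
SQHEHLP-ENNQHFQQDCWDWFGQ-EPAVLGFFQTFKEYTATDYSAVEHMEQPRWELVGYQNTWITPAYVIECVDQMANNCY-PSLGIEDSSHI-VLPFGTDRFTSVFGTQNATHDRELFFNYMECPDTPIKGSHIGTA-YPQ--FLRTRYKFSCNCKGSCFTVDTKSCDCTTGMKYK-A
>terl_05
HMHWHSYWFPNQHFMQDCWHWAGQYWPHNLGFFDTFDEYTA-PYSNFLHMHQPRWELRNELFTWITP-TVI-CCDQMQDNWY-PSVGIEDSSHI-VLPKGTLRFDRVFGSQCDTHHVELQFNIDEWYNTGIPGLMIGPA-VPQ-SFGRDIAKFSCNSMGSCFCQDTNSNSCTTTMKYTTA
>terl_06
MQHAHQY-ENNGHNHQHCWHEWGQ-APANLGFFETFDNYTATKGSSLKDMEIPRWERATVQPTWITPAITI-CCDQMCPNIY-ISVGIEDSFHIVVLPKGTDRFTNVFGDNDDTHEEELQINIDECVDTGIQGMHIGPA-HPQ--FGRYYIKFSCNRPGSCFQVDTKSNTCTPWMKYT-A
>terl_07
MQHFHVEWYNNQHFMQHCWHWFGQ-EPAFLGFCMIFRLYTATDYSHVKHMEQPRWERFLEGNTWITP-TVI-CDDQMQNNIY-SSDGIEDSRHI-VLPKGTLRFTWVFGKHSITHPEELTFNFDEHTVTWIQGTHIGPA-VPQT-FGRVRTKFSCNEKGSCFYVDTLSYSCTTNRKYI-S
>terl_08
PMHKHNT-CNNQHFMQHAWHWFGQYEPRALGFFRTFEEYTA-DYSNPNHMEQPFWEIVCVTNTWITP-MHI-CSDQMYCNIYRPSVGIEDSWHIVYLPKGTDREIWVFGGPDDTHEWELQFNMDEYEATFAPWYHIGPADVPQ--FGRGLAKFSCNCKGSCFYVDTKSPMCTNNNKYFWR
>terl_09
PEHTHNYWENNWDFMQCCWCCFGQ-EPAGLGFDQTFDEYTQ-WTSNVKHMLQPRWELVTEMNTWITP-NHI-CWDQMGDNIY-PSIGIEDSHHI-VLPCGTDRTTLVFGSVCATHEVELAFNPAEWVDTTRFPLHIGPADVHQTSFGRWRAKFSCNENGSCFCVDTKSKSCTMNMKYT-A
>terl_10
PQHQHNY-HSNQHRMQACWHDPGQYAPTGLGFFDFFSEYTCTDNSSVKHMEIKRWEWDDEQETWITP-YVI-CCDQMHYNIY-PSCGIEDSGHI-VLPMGTDRFTWVFGSWYITHEVELQFNPREDHDTGIPYLSIGIADVPQTSFGRWRAKFSCNKYGSCFWVDTNSDFCTWIMKYA-A
>terl_11
GQHAHNE-ENNQQFTQHCWHWFGQYAPAGLGFVDTFVAYTD-DQSMVRHMEQMKWELVDEQQTWITPWMVIECCDQMQHNIY-ASVGIEDSLHIVALPPGTPRFTAVFGSKCDTHTTELHLNPSEWVDTGCPGGEIGPA-VDQT-FGRGRAKFSCNDMGSCFCKDTKSRSCTLNCKYT-A
>terl_12
PQHMHNG-CSNQGFMQYFWEQMGQ-EPQQLGFCDCFDTYTA-DFSNVKLMLYQAWELVTCNNTWITPATTI-CCDQMQINYY-PSVGIEDSRHI-VLPEGTDRFQWVFGWDDKTHYCELKANPDEQVMTYIPGPHIGKA-VPQT-FSRSSAKFSCNTKGSCFGVDTMSNSCTWNMKYLKL
>terl_13
SQHKHFY-VDNQHCGQHFWQWFGQ-QPAVLGFFDTFSEYTA-DYSDVFHMEHFRWEQVTMQNTWITP-TYI-CCDQMQNNIY-PSVGIEDSSHIVTLPKGTYRMTRVFGLYDYTHGRELLFNPDEFVQTGGLGLHIGPA-VSQT-FGRGGSKFSCNEKGSCFCEDTTSNDCTWNMKYT-A
>terl_14
AQHFHNY-CCNQHTEQHQWCWFGQYEPPPLGFADTFDEYTATYYSNLKHMTDPRWEWVDEFNTWITPASVIECHDQMRDNCY-NSYGIEDSQHIVVLPKGTTRGTWVFGSEAQTHDWELEFNPDEFVFTGIPCLKIGPADLPQ-SFRRGRAKFSCNVPGSCFEVDTKSNSCTHLMKYW-A
>terl_15
PQHAHINWESNQPFMQHFWHKTGQYEPAVLGFHDAFIFYTK-DMSHNVHMEVFRWENPDEQYTWITPITVIECGDQMTDNRY-ISVGIEDSRHIVVLPKGTPRFSYVFGSVDDTHCVELQQNPDEANQTGVPGVPIGPAPVTDT-FGRGTYKFSCNEKGSCFFVDTPSNSCTFNSKYD-A
>terl_16
PFHYHNYWALNFHFMQHDWHWMGQ-TPADLGFFDTFDMYTA-DMSNLGHMEQPKWELVTQQNTWITP-THIECTDQMQNNIYEPSSGIEDSRHI-ALPVGTHRFCYVFGWWDSTHEVELQRNPDEYVDTGYRKHHIGKADFPPTSFYRHVAKFSCNWWGSCFCVDTKSNSCTTVNKYTCA
>terl_17
YDHAHNM-INNQHFMQNTWCWWGQ-VPATLGFFNWFSEYTATDMSFVKHMEIPRWELGTEQCTWITPEHCI-CCDQMQLNIYRDSVGIEDSNHI-VLPRGTWRFYCVFGFHHGTHNVELHFNPDEWVQTGIPQLHIGPARPPV-SFGRKRAKFSCNFRGSCFCVDTKSISCTHWMKYCKY
>terl_18
HQHAHNE-VGNVIFMQVCWFWWGQ-EPRGLGFYWEFDEYTA-DYSFVFYMEQSRWELVTEQNTWITP-TFIECYDQMQSNIYKESVGIEDSQHI-NLPPGTIRCTRVFGSLRDTHQVELWFNPTERLDTCMRGEHIGPAWTFQT-FGRPRAKFSCNAKGSCFCVDTKSNSCTTYGKYLVA
>terl_19
PQHNHQKWEWNQHFLQHIWHWRGQYEPAGLGFDDRFGEYTN-DYSYVKKMEEYCWELVNETCTWITP-TVIECSDQMQDNFY-WSSGIEDSIHIVNLPKGTERFNWVFGRTDDTHTVELQFNPIEWVFTKIPGLAIGDAIKHK--FGRKRCKFSCNYSGSCFSLDTCSNHCTFNMKYTEA
>terl_20
PQHYHNY-ENNQFFMQHRWCWFGQ-WPDYLGFAMTFSEYTR-DCSEGKHMKYYQWELVQEQNTWITP-LVIECCDQMEGNIYRPSVGIEDSRHIVKLPKGTDRFPWVFGSQLDTHDVELQGNPWEWVDTEPCGKHIGPA-PYM--FDRGFTKFSCNPKGSCFCTDTKSNSCTTNMKYF-A
>terl_21
PTHAHLYWENNFKFPQGCWHWFGQYWPRGLGFFSTFVCYTATYYSHPQIMFELRWEVATVVNTWITPFLVI-CCDQMQDNYYWPSVGIEDSRHI-DLPKGTDRQTWVFGSVDVTHMVELQNNPREWVDTGLPDNHIGVACIPQT-FGRGTWKFSCNGKGSCFCIDTKSNSCTTNMKYHKL
>terl_22
PKHMHNYWLNNNHAQQNCWPWFGQ-FPAGLGFFVLFDEYTATPYSNHNHMEQDYWEVYTEYDTWITP-TGI-CWDQMGQNIYRPSAGIEDSRHI-GLPMGTDRNQWVFGRLDNTHEVELRQNWDEYQQTNIPEPHIGPA-TIQ--FGRRRAKFSCNIFGSCFCKDTKSNSCTGDMKYP-A
>terl_23
TYHVHNY-KNNQHPMQTCWLYFGQ-EPYALGFKDTFDEYTATCCSNIRHMINPRWELYTEQNTWITPFMVIECVDQMLLNIYRPSVGIEDSRHIVVLPKGTDRNTFVFGSDLVTHEMELRFNVDEWVWTTIGGLHIGEA-VGETSFFRPRAKFSCNWKGSCFCKDTKSNTCTTNWKYR-A
>terl_24
CIHAHNYWELNVIFMQHYWHWCGQYEPAGLGFFVTFLSYTKTCVSNNKNMKQYEWELEHQDNTWITP-DVI-CCDQMTINIYNLSVGIEDSRHI-ELPKGTWRFTPVFGYQQWTHMVELGFNLDEIVSTGMPALFIGPA-VWQ--FPRWKAKFSCNEEGSCFHVDTKSNSCTTNMKYP-A
>terl_25
PQHGHPY-ENNVHFMQFLWAWFGQ-LPVPLGFFDTFDEYTA-DYSWSKRMNQRMWERVTEQVTWITP-TNI-CCDQMNDNIY-PSAGIEDSHHI-WLPTGTDRWTWVFGSCDDTHGDELCFNPDEWVDTGYHGLHIGNAYKPQ--FGRGQAKFSCNEKGSCFCVDTWSPSCTQNMKYFTV
>terl_26
PHHAHCG-ENNQHFMQPCWSWFGQYTPGGLGFFKTFVGYTV-ECSNVLHMHQESWEGVTERYTWITP-RVI-CFDQMTYNIY-MSDGIEDSKHIVVLPKGTDRFTWVFGDQDTTHWVELQSNPDEEVRTNNDGLHIGPA-RPQTSFGRARAKFSCNEKGSCFTVDTHSLSCTDHNKYTKF
>terl_27
PQHWHNY-ETNQHFMQHTWQHFGQ-WPWGLGFFWLFADYTE-DYSNWKHMELQLWELVTIWNTWITP-PVI-CCDQMQINIY-FSGGIEDSFHI-VLPGGTWRKNWVFGSQDDTHEGELQANADEKVDTGNPGLHIGPAVIPE-SFGRGRAKFSCNEKGSCFCSDTHSHSCTTNMKYT-A
>terl_28
TQHNHPY-EMNIHFPQSCWHSAGQ-KPAWLGFHQTFMEYTA-DYSLVVHMEQPFWELVTEHTTWITP-TEIECCDQMQPNIYFPSLGIEDSSHIVALPTGTGRFWDVFGSFSTTHPVELQFNPDETGPTGIAPLGIGWA-VPQ--FTRWMAKFSCNEPGSCFCVDTKSHSCTTAMKYT-K
>terl_29
PQHAHNYWENNQCFMQQHWTKAGQ-EPPGLGFFDTFDMYTITDYSPVWHMEQGEWELPTTQQTWITPATVIECCDQMQDNIY-HSVGIEDSWHI-YLPPGTQRGTPVFGSQPPTHDVELQKNPDEWVDTRIPYNAIGPA-VVQ--FPRGRLKFSCNEKGSCFTVDTKSHSCTHPMKYTKC
>terl_30
PSHGHNY-EDNFSFMQNCWHSTGQYNPAGLGFFDMFDEYTA-PQSNVQHMEWPRWELVTCQTTWITP-TVI-CCDQMQDNAYIKSVGIEDSSHIVVLPLGTCRFTWVFGSKDDTHEVELQRNLEERVSTGINATHIGPA-ALG--FGRCDLKFSCNESGSCFCVDTKSNSCTRNMKYDKA
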