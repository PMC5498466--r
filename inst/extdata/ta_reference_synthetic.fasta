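>relE_1|relE|toxin
TAKFRTIYVVKKSLDPRTTRIVPILIFHNLSIKYRQVFHATYYKLGSWMPMAQHAKIVEA
KTTGAKNQMKLSRWLHLGQKKEPL
>relE_2|relE|toxin
TAKFRTIYVVKRSDDPRTARIVPILIFHTVSIKSRMVAHVSYDKLCSWMPTLQIAKIVEA
KTRLAKNQMKFTRWLHLGKKEEPL
>relB_1|relB|antitoxin
YEEDLLGDANGPDDALSGSSLFENLEEGSVDNVIASWEELVIDGGDDSPDVGPDAPFGEA
EESDDMIAEDISE
>mazF_1|mazF|toxin
GRHHGRVPFVGWVRIRTIGSIIRIMCKTKVPWSENHFCGGKKFAKLHRISKGAKGSCAVH
PGPRKTVRIPSRKAYRERNFMGIKQEIQNCAPRRSKLSKIKGRTASKAKKL
>mazE_1|mazE|antitoxin
EFDRQNKTPVSCSIVDGISDAASQQVEELGPHGGGITLDSEENTDIKEEIEEAEDGDDTE
TIVNEDDWVSDGDFAEWLARMS
>yoeB_1|yoeB|toxin
NLYSQLPYLMKIGCHKVKDQGGAMAVATKGRDFVYGSSAHLERSLCKSLNPNNRFPHAGA
YAHAHTKEHKYNKGFRKMCKGKPRSSKW
>yefM_1|yefM|antitoxin
AVIDDNLTCHEEESEEEKSEDDNDNADSAGNEIIGTNMSAEEEVDGMSDGDDPDFCDPEP
ADETAIVDHHVSSEDSTIYSSAE
>vapC_1|vapC|toxin
GAHTVKNLRAKKGNGENDIVSGGRMKAQTHIHRCRQKTDQLRKVYREARGCKVVTRRPRA
PWGIKTGIPKSKHFRVSLRKKDRARQPNKRQSLHKLGSKSRINEGKLRQTVAGATHQFLS
NAHTEKNIVK
>vapB_1|vapB|antitoxin
VVLNAGYVLEEMEAKDTDVEDSHSPEAEDPPDEPDEPEGNSIKPAEEGSNDDDASDFHAE
EGDDSEVASEGDKEDDDA
>vapB_2|vapB|antitoxin
VVLNAGYVLLEMEAKGVDREDSHSPEEELPPSDPGEPAGNSILPAPEGSNNDDFSDIHAL
EGDDFEVESEGDNQDDDA
>doc_1|doc|toxin
KKARPSFILKFWRSKGQRDQCKAAPSKHVKRIHKPPKVKNRSAHLRPPTSGKPQKMSKAK
HRRTVLVIGGTIRSLYRRKTGKVDHREVAKPGAKYRLKRLRASLHKKHLSYKSVNGKRVI
>phd_1|phd|antitoxin
ESAEGTGAQDYEEESIAMTVLADCQPGGRGYDNLWEEGDENDTDPVVAISSEEWDMDDNE
SEQDDEPNEKFFS
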