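>S_frugiperda
NTYHEIEFKWDLGSLILDMMYRYNNHMMSDLFHKQHMFVSAKQEFRADHYRFLDVPRNWH
EARDDMMNFVEIVPNVVCLKSCPCQMEMTAKFFFDFFIFCNAGQRITIFIAMENMTGYNC
MKYHLYFQRGWCKEVGYAHWSIFHSMIRNWIFTCVLFPKFSSCGPGKEHYCESTWPHNNC
KGQFHQRPGWMHQTEELITDGPEKNGANSLYAMMMGHGTSECCSGYDQWRHWSIFARIHN
GPIVWGGMESKAINIQSNSMEHKYLGSFCCMKPDYYNKFMFCILQQVMLCQLPFVTPENI
VVKWKYLGKIVWKLSDHGGMWTHHMHIEPDPDYLPELWAKSMTFHMNGFCGGPPCCDWWV
GWERTSLTKRFKIGAYPPDPNRGFLPFIQTHMLMHYSDLELCKYMTPQTIVRAGSRDHLS
AQHDVFEVMLRTYNWPKLFCRTQRLMPWVSRRPSSTDLPNNFFAQERDTPCCSPVIRYLK
HPFDCHALQWPHGPHCATKGCIKADYWTHGSVWAMKEAYIRSPPCHQNNDMQLDYTMCYG
IHDPYEKRLKMSTMFKNTDNP
>B_mori
NTYHEIEFWWDAGSRILDQMYRYNYHMMSKLFHKQHMFVSAKMEFRASLYRFLDVPRNSH
EARDDSMNFREIVPHVVCLKSCPCQMEMTAKFFFFFFIFCNAAQRQTFFIAMRNMTCYNC
MKYHLYFQRGWCKFVGYAVWSVMHSTIRNWIFTCVLFPKFSKCGPWAPHYCQSTWPHNNC
KGQFHQRPGWMHQTEELITDGPEKNGDNLLYAMMGWHGTSECCSGYDYWRHSSIFARIHN
GPMVWGGMESKAINIQSYSMEHKRLGSFCQMKPDYYIKFMFHWEQQVMLCQLPFVTPEMI
VVKWKYLGKIVWKLCIHGGMWTHNMHIEVDPDYLKELWAKSHTFHMPGFGGGCPCCDWWV
GWENTSLTKRFKIKAYPPDPNRGFLPFIQTHMLPHTSDGELCKMMTPNTIVRAGSRDHAS
AQHDVFGVMLRTYNWPKLFCRTQRLMPWVSRRPSSTDLPNGFFAQERMTPCCTPVIRYCK
HPKDCHALQWPHGPHCFTKGCIKADYWTHLSVWAMKECYIRSPPCHQNNDMQLDYTMCYG
IHDPYEKRLCMSTMFKNTDNP
>C_pipiens
DSRNQIEFWWDAGYRSNDQVRRMPNTQAANLEHHPQSFESAKQTFSADPYRTLVLKRNRM
FGRYDMNLFIRIAPECWWLSSNPHCMTHWPKFGEFFQQFWIQHGCMTIFIIMAEMTYYNA
NKSFWYFQQGWWDHVRYAAWTLWHFAIRKWIGKMVLFPGFRAMKPSKPHHCPGDWKHPQC
KQDEHIRFVHMKMFAELITDSPNSGNRDETYFIYMWNGTSCCCSGYIQTRNDSIFWFIFN
WGMSWGGNYSKLIVIWHIHTMHKYTLSFLKLKPDRYTKFMFHIEIRVVLQVLPIVGPEMI
VVKWSYDGKIDHKSCTLGGACKWWMCEYVYPDYLNKKWAKMMTFHKNFPGAWCPCQDVIV
YYKATWLTWATHIIRYVSDMNRGHEPFICTCMLYHTFIIEKCNMMTWQTLVVSGVRNHLS
AEWTEMSLQLGRPNWPYLYWRIMRILNWVICRPSFHANPRGFFAQQTSTPWPTCVIPYCK
HPFDPHWIQRMHGPREATKWCIKADVWDFGSMIISMTAKIVLPPCHQNSDYMLDALPNFG
GKEPREARLCQSTSFKNTDIP
>H_sapiens
DEYCEIQKQWDAGWRVLFQMWRNPNMQASDLFNCPRMFVSAKIHFEAPHYNFLSVPRNWI
VARYRMNPTVEIVPHENTLTSCPHLMEHTPKFGFFFHMFWIRHERITIYIAMREMTVYNC
NKSTLYQCRKWCKEVRYIVCYLYHFLIRNWIEAMVTFFKFSPGGPVKPHVCQCTWCHPNC
KGHFHATFHWMKYWWELITAMPESRGCAEIYWMMRWHTTYECDSGYDQTRHASIFALMMN
GPESWGGRESKAILIWGLSDEHQYLYSFCKLKPDYYDVFRAHIEQCNVLQVLPIHGPEMI
VWKWKYLQKIVHKLCTIGGAKKWNMHEGVPDDYLNEQWALMMTQHSNSPYCECPCQTWAV
YWGFIIRVKRFKIITLVQDPNGGYDPFHFQHMIHRTSIAEYCNMMCPQTIVRSPHRNHLS
AFDTTFGWQLMTPNWPKLECRTQRRFNQVSWRPSFTAYRNVFFLQETSWPWPTRSTTYLK
HFFDCHNILWWGGPHCATKGCSKADEWTHMFVSNMMECRIRLPPCHQFSDYQWDAQMRIG
IHCRREKRHCESTSFKATDNP
>B_taurus
DEYHAIQFQYDTGWRVLFQRERNPNNQMSDLFNCPRMFVSAKIHRRADHYNPLSVPRNWI
VARDDMNPTVVIVPHENTVLSCPHLMRHCPKFGFFFHMFWIRHERITIYIAMREMTVYNC
NKKLLYRFRKWCKEVLYIVWYLYHFLIRNWCGAMVTFFKFSATGPVKPHVSQCTWCHPNC
NGQFHATFIWMKYWWELITASPESRGCAEIYTMMRWHTTYECCSGYDQTRHAGIFALMMN
LPESWGGRSSKAILIWGLSTEHQYLYSFCKLKPDYYDVFRAHYEQQNVLQVCPIAGPEMI
RWKWKYVQPIVHKLRTHPGAWKWNMHEGVPDDYLNEQWAKVMTQHSNFPYYGCPCQTWAV
YWGFIIRQKRFKIIRIVQDPNGGYKPFHFQHMIHHTGIAEYCNMMCPQTIVRSGKRPHLS
AFDTTFGWQLMTPNWPKLECRTQRRMNHVSWRPSFTACRNVYFLQETVWPWPTRSTTYCK
HPFDCHNILWWGGPHCATKGCSKADRWTHTFDSWMMECRIRLPPCHQWSDYQFDQHMRYG
IHCRRRKRHCEGTEFKATDNP
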