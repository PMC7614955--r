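>group_i_ref_1
TFALEVERHLRQKVRDKRFPFYCPDALMRLEEVPFDCVWTVGMAQDCGLIFKTHDPLEDY
HMDSHRFCVTEFQLIKEHLSPWSTPMMSIGRPAGKSMLNFCTQIRGNMFSTQVCSGGYRP
LPKSCCVQHYLLLTTFMQDAFDPMYTYEDMTKTGLYITPCISQFMQAWFLGSQHKKDVVR
YSAGSKYPSSRVGAQSDMVC
>group_i_ref_2
DFALQVYRHLRQVVRRKRCPFYCIDALMRAEEVRFDCVWTVGMIYSCGGIFKNHGPLKNY
KNDSHRMCVTEFQLIKEHLVPWSTPLMSIYLPQFKSMLNACTQTRGRMLSTIVCSGGYRC
LNKACCVYHYLFLHTTMQQAFDPMYTIEPMTKTGAYATACISDFMQAWTLNSQHKKDVRR
YSAGMKYPSMRVGAQSTMVM
>group_i_ref_3
TFALEVERHLRQYVRDMRFPFYCTDALMCIEEVPFDCVLTVGMAYDCGLRFKTHGYLKEY
KMTSHRFCVTEFQLIKEHSSPWSTPMMSIGRPQFKSMLNACTQTRGRMFSTQVCSGGYMC
LNKACCVQHYLFLTTFMQQAFDPMYTYYPLTKTGAYATACICDGMQAWFYGSMHKKDVRR
YSAGMKYPSMRVGAQSTMVC
>group_i_ref_4
TFALEVERHLRQYYRDKRFPFYCIDASMRIEKVPFDCVWTVGDAYDCGLIFKTHGPLLNY
KMQSHRFGVTEFQLPKEELSPWSTPLMSDGRPQFKSMLNICTGTRGRMFSTVVCSGGYRC
LNKACCVQHYLMLTTPMQQAFEPMYTYEPWTKTGAYATACISDDMQARFPGSQSKDDVRG
YSAGMKYPSMRVGAQSTMVC
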