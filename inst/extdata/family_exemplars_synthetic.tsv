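family	class	sequence
Cdx	ANTP	EGSTYFEVISRWRYIHHQGGQKRGPAQTERDFHYQWCHMIMDVIMPCNLQNNSGREYNHF
Hox1	ANTP	EGSTYNEVISVWVYIHHQTGEKRVPAQHHHLFHYQWCHMIMDWIMCCNLQNESGREYNHA
En	ANTP	EGSTRFEVISRWPYIHHQTGEKRGPAQTHRLFAYQWCHMIMDVIWCCNLQNVSGREYMHA
Msx	ANTP	EGSYYFEVISRVRYIHHQTGEKRGPAQSHRLFHYQECRIIMDWISCCNLQNAMGREYNHA
Nk5/Hmx	ANTP	EGSTYPEVSSRWRYIHGQTGEKRGPAQTYRDFWYQWCFMIMDNIMQCNLQNASGRIYNHA
Gsx	ANTP	EGSTEFEVISRPRDIHHQTGEKRNPAHTHRLFHYQWCHMIMDWIMCCNCQNASRREYNHA
Dlx	ANTP	EGSTYFAVIIRCEYAHHGTGEKRGPSQTHFLFHWQWCHMIMFWIMCHNLQNAFGRETNHA
Emx	ANTP	EGSTYFEVISRWRYIHHQTGEKRGPAQTHRLFHYQWCHMIMDCIMCCDLQEASCREKNHA
Gsc	PRD	ENVPYRPVMSRWREIYHQTMMWRRQIQGHMLPWSTLSHMIEDMIMWCNRKWPRDTRNNLA
Mix	PRD	ENVPYQVVMRGWREICHQTMMWRRQIQGHHLPHSTGGHMIEDMIMYCNRKWPMGTRNNLA
Otx	PRD	ENVMYRPVMNRWRENHHQSMMWRRQIQGCMLPHSTGGSMIELMIMCCNRQWWMGTRNYLA
Pax4/6	PRD	ENVPYRPVMSRWRERCHQDMMWRRQLQGHMQPHSTGGHMIEDMIMCCNDQWPMGTRANLA
Arx	PRD	ENQPYRPVMSRWREICHQWVGWRRQIQGHMLPHSTGGHMIEDMIMCCNRQWPMGTRNNLE
Lhx1/5	LIM	EFCPNRHVWRRLRDWREQKDELRGQYGNHRLCSYQWNHKKPEQEMCHDRQTTSSSPHNHT
Isl	LIM	TFCPNRDCMVRMRDWHHQKDELRGQYGNHRTSSYQWCFMKNEQEMCCNRQTTHSSPNNHA
Pou3	POU	LPAAYPPLNLRWRDPHHQTDMARGQYQNHKLWIKCSMHMIMAKCYQVLQQTELSLRYSHA
Pou4	POU	LIAAYPPVNLRVRDIHHQTDEARGQYQNHKLWIYCSMHMIMAKCYQKNRQTMSGSRYSLA
Hnf	HNF	VGAPTRPFMSRFYDVIHPTDEQFDQDKNHTYCHEQWCYMIRDWIMGCKRQALSSSAINLA
Six1/2	SINE	EVAPMRQPHSRMRDIHDQRDNLAGWYVNHRLIRQQWKHMWGDMILTCREKTPSKSRYNIA
Six3/6	SINE	HVAPFGVPMSRMVDIHVQRDNLAENYVNHRTFFCQPCAMQGDNILTGNRKTPSKSRYNHG
Meis	TALE	EGAPYVDKMSRWGDAHDQIEEIRGQTWNHALSHYQICMMIMDWIHCCVRGTPCNSDYYHK
Pbx	TALE	EGQPYVYKMSRWWDAHKQIEIIRGQIQKLALSHYQICHWIMIWIHCCKRGTDQNSMFYSV
Irx	TALE	EGAPYVQKMLRWGDAHHQIEEMRRDIQNHALSHYQICHMVMDWIHACVDGTPQNFMYYHK
Cux	CUT	EGVPYEPLMSGWRQIEHQTDELRGQKQNHRCSHYQWCWAIMDFIPCEWRHTGFNISYNRI
Onecut	CUT	EGVVYRPVMSGWRQIENNTHELRGQKANHRCIHYQWCWAIMDFIMCCNRQTPCNIRYMRI
Prox	PROS	PCWPYRWVMRMWRDHHHQTQELRMRYQLVRHYHYYTCHEYWDWIMCCEMQTPSFSSFKHE
Zfhx	ZF	CGAPYVPKMQRYRDIHMQDLELRGLSQMAFLSHPGKCHMIMFQEMCAEHQTISGSIYNQA
Cers	CERS	EEVPKRYYHSAWRDIHHQTDELTPQMQPRPLHELQWRDMIMDYQMCCNRQTPSGSRYNHA
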