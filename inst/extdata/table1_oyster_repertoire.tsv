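class	family	gene_name	gene_model
ANTP	Cdx	Cdx	CGI_10023003
ANTP	Evx	Evx1	CGI_10013056
ANTP	Evx	Evx2	CGI_10013058
ANTP	Gbx	Gbx	CGI_10012203
ANTP	Gsx	Gsx	CGI_10015548
ANTP	Hox1	Hox1	CGI_10024083
ANTP	Hox2	Hox2	CGI_10024086
ANTP	Hox3	Hox3	CGI_10024087
ANTP	Hox4	Hox4	CGI_10024091
ANTP	Hox5	Hox5	scaffold801_482925_483164
ANTP	Hox6-8	Lox5	CGI_10026565
ANTP	Hox6-8	Lox2	CGI_10018592
ANTP	Hox6-8	Lox4	CGI_10026562
ANTP	Hox9-13(15)	Post1	CGI_10027385
ANTP	Hox9-13(15)	Post2	CGI_10027388
ANTP	Meox	Hrox	CGI_10014888
ANTP	Mnx	Mnx1	CGI_10026625
ANTP	Mnx	Mnx2	scaffold313_810611_810757
ANTP	Pdx	Xlox	CGI_10015546
ANTP	Barhl	BarH1	CGI_10009941
ANTP	Barhl	BarH2	CGI_10009942
ANTP	Barhl	BarH3	CGI_10009943
ANTP	Barx	Barx	CGI_10004014
ANTP	Bsx	Bsx	CGI_10008107
ANTP	Dbx	Dbx	CGI_10002480
ANTP	Dlx	Dlx	CGI_10016653
ANTP	Emx	Emx1	CGI_10018603
ANTP	Emx	Emx2	CGI_10025052
ANTP	Emx	Emx3	CGI_10025053
ANTP	En	En1	CGI_10012208
ANTP	En	En2	CGI_10012209
ANTP	Hbn	Hbn	CGI_10011181
ANTP	Hhex	Hex	CGI_10025054
ANTP	Hlx	Hlx	CGI_10013972
ANTP	Lbx	Lbx	CGI_10010398
ANTP	Msx	Msx	CGI_10023979
ANTP	Msxlx	Msxlx	CGI_10013606
ANTP	Nk1	Nk1	CGI_10025189
ANTP	Nk2.1	Nkx2.1	CGI_10021129
ANTP	Nk2.2	Nk2.2	CGI_10026839
ANTP	Nk3	Nk3	CGI_10023919
ANTP	Nk4	Nk4	CGI_10019417
ANTP	Nk5/Hmx	Hmx1	CGI_10013448
ANTP	Nk5/Hmx	Hmx2	CGI_10027035
ANTP	Nk6	Nk6	CGI_10028825
ANTP	Nk7	Nk7	CGI_10027184
ANTP	Noto	Noto	CGI_10013404
ANTP	Ro	Ro	CGI_10005958
ANTP	Tlx	Tlx1	CGI_10020596
ANTP	Tlx	Tlx2	CGI_10020599
ANTP	Vax	Vax	CGI_10020700
ANTP	ANTP_NKL Clade I	Cgi_NKL	CGI_10028802
PRD	Arx	Arx	CGI_10028810
PRD	Dmbx	Dmbx	CGI_10011833
PRD	Drgx	Drgx	CGI_10007626
PRD	Gsc	Gsc1	CGI_10007832
PRD	Gsc	Gsc2	CGI_10026711
PRD	Gsc	Gsc3	scaffold42840_31020_31181
PRD	Hopx	Hopx	CGI_10009529
PRD	Otp	Otp	CGI_10021751
PRD	Otx	Otx	CGI_10015784
PRD	Pax3/7	Pax3/7	CGI_10026438
PRD	Pax4/6	Pax4/6	CGI_10020873
PRD	Pax4/6	Pax6	CGI_10027695
PRD	Pitx	Pitx	CGI_10018398
PRD	Prop	Prop	CGI_10006125
PRD	Prrx	Prxx	CGI_10021523
PRD	Rax	Rax	CGI_10028663
PRD	Repo	Repo	CGI_10005826
PRD	Shox	Shox	CGI_10012343
PRD	Uncx	Uncx	CGI_10007529
PRD	Vsx	Vsx1	CGI_10010562
PRD	Vsx	Vsx2	CGI_10010563
PRD	PRD Clade IV	Cgi_PRD1	CGI_10017003
PRD	n.d.	Cgi_PRD2	CGI_10012650
PRD	PRD Clade VI	Cgi_PRD3	CGI_10009720
PRD	PRD Clade V	Cgi_PRD4	CGI_10003333
PRD	PRD Clade V	Cgi_PRD5	CGI_10013213
PRD	PRD Clade I	Cgi_PRD6	CGI_10015407
PRD	PRD Clade III	Cgi_PRD7	CGI_10025814
PRD	PRD Clade II	Cgi_PRD8	CGI_10026008
PRD	n.d.	Cgi_PRD9	CGI_10026078
LIM	Isl	Islet	CGI_10028355
LIM	Lhx1/5	Lhx1/5	CGI_10025343
LIM	Lhx2/9	Lhx2/9	CGI_10015423
LIM	Lhx3/4	Lhx3/4	CGI_10028171
LIM	Lhx6/8	Awh1	CGI_10025669
LIM	Lhx6/8	Awh2	CGI_10020871
LIM	Lmx	Lmx1	CGI_10019449
LIM	Lmx	Lmx2	CGI_10019450
POU	Pou2	Pou2	CGI_10006547
POU	Pou3	Pou3	CGI_10005968
POU	Pou4	Pou4	CGI_10023764
POU	Pou6	Pou6	CGI_10028901
SINE	Six1/2	Six1/2	CGI_10009922
SINE	Six3/6	Six3/6	CGI_10027570
SINE	Six4/5	Six4/5	CGI_10022945
TALE	Irx	Irx1	CGI_10011883
TALE	Irx	Irx2	CGI_10028533
TALE	Irx	Irx3	CGI_10020098
TALE	Irx	Irx4	CGI_10004700
TALE	Meis	Meis	CGI_10019589
TALE	Mkx	Mkx	CGI_10011802
TALE	Pbx	Pbx	CGI_10026001
TALE	Pknox	Pknox	CGI_10011944
TALE	Tgif	Tgif	CGI_10023491
TALE	TALE Clade II	Cgi_TALE1	CGI_10000035
TALE	TALE Clade I	Cgi_TALE2	CGI_10008335
TALE	TALE Clade III	Cgi_TALE3	CGI_10011283
TALE	TALE Clade VII	Cgi_TALE4	CGI_10013112
TALE	n.d.	Cgi_TALE5	CGI_10014640
TALE	TALE Clade V	Cgi_TALE6	CGI_10019516
TALE	TALE Clade IV	Cgi_TALE7	CGI_10015054
TALE	TALE Clade IV	Cgi_TALE8	CGI_10015055
TALE	TALE Clade VI	Cgi_TALE9	CGI_10015742
TALE	TALE Clade VI	Cgi_TALE10	CGI_10019518
TALE	TALE Clade VI	Cgi_TALE11	CGI_10021477
TALE	TALE Clade VI	Cgi_TALE12	CGI_10021478
TALE	TALE Clade VI	Cgi_TALE13	CGI_10015317
TALE	TALE Clade IV	Cgi_TALE14	CGI_10021576
CUT	Cmp	Cmp1	CGI_10015221
CUT	Cmp	Cmp2	CGI_10015220
CUT	Cux	Cux	CGI_10022123
CUT	Onecut	Onecut	CGI_10019668
CUT	Cut Clade I	Cgi_CUT1	CGI_10006727
CUT	Cut Clade I	Cgi_CUT2	CGI_10022104
PROS	Prox	Prox	CGI_10022026
ZF	Zeb	Zeb	scaffold42570_54922_55110
ZF	Zfhx	Zfhx	CGI_10012804
ZF	Zhx/Homez	Homez	CGI_10009971
ZF	n.d.	Cgi_ZF	CGI_10018873
CERS	Cers	Cers	CGI_10021077
Others	n.d.	Cgi_Hbx_1	CGI_10004542
Others	n.d.	Cgi_Hbx_2	CGI_10016179
Others	n.d.	Cgi_Hbx_3	CGI_10007234
Others	n.d.	Cgi_Hbx_4	scaffold1627_218521_218706
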