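character	kangxi_index
一	1
不	1
上	1
下	1
三	1
丁	1
万	1
与	1
为	3
主	3
丸	3
乏	4
久	4
乙	5
九	5
也	5
乱	5
予	6
事	6
了	6
二	7
人	9
使	9
停	9
伴	9
偏	9
休	9
体	9
件	9
例	9
供	9
位	9
住	9
作	9
依	9
价	9
余	9
今	9
儿	10
克	10
元	10
先	10
光	10
免	10
入	11
内	11
八	12
公	12
共	12
关	12
兴	12
典	12
再	13
册	13
冖	14
冠	14
写	14
冫	15
减	15
冷	15
冻	15
凉	15
冰	15
准	15
凵	17
出	17
凶	17
刀	18
分	18
剂	18
切	18
划	18
刺	18
前	18
利	18
别	18
到	18
刻	18
剧	18
力	19
加	19
动	19
助	19
势	19
功	19
务	19
匕	21
化	21
北	21
匚	22
匹	23
医	23
区	23
十	24
升	24
半	24
协	24
南	24
华	24
卜	25
卩	26
即	26
却	26
厂	27
压	27
原	27
厚	27
厌	27
厅	27
厶	28
去	28
参	28
又	29
反	29
发	29
取	29
受	29
双	29
变	29
及	29
口	30
后	30
呕	30
吐	30
呼	30
吸	30
嘱	30
司	30
唑	30
呋	30
告	30
合	30
名	30
吃	30
号	30
味	30
咳	30
和	30
囗	31
因	31
国	31
园	31
土	32
地	32
塞	32
基	32
场	32
坏	32
型	32
城	32
增	32
境	32
块	32
均	32
坐	32
士	33
夂	34
处	34
夊	35
复	35
夏	35
夕	36
多	36
大	37
天	37
头	37
失	37
奥	37
太	37
夫	37
央	37
夹	37
女	38
好	38
妇	38
始	38
子	39
孢	39
孔	39
学	39
孕	39
宀	40
察	40
寒	40
宁	40
安	40
定	40
室	40
家	40
宽	40
实	40
完	40
宜	40
寸	41
对	41
射	41
封	41
寻	41
导	41
小	42
少	42
尢	43
就	43
尤	43
尸	44
尿	44
局	44
层	44
居	44
展	44
屈	44
山	46
岛	46
岁	46
峰	46
川	47
工	48
左	48
差	48
巨	48
己	49
已	49
巴	49
巾	50
布	50
常	50
帮	50
带	50
市	50
师	50
干	51
年	51
平	51
幸	51
并	51
幺	52
广	53
应	53
床	53
度	53
庆	53
康	53
序	53
廾	55
异	55
开	55
弃	55
式	56
弓	57
张	57
强	57
弱	57
弹	57
彡	59
影	59
形	59
彩	59
彳	60
往	60
律	60
得	60
心	61
患	61
感	61
急	61
恶	61
悸	61
想	61
情	61
意	61
恢	61
态	61
忆	61
性	61
戈	62
战	62
我	62
成	62
或	62
戒	62
户	63
房	63
所	63
手	64
拉	64
振	64
提	64
报	64
打	64
扎	64
抗	64
护	64
抢	64
抽	64
拔	64
持	64
换	64
排	64
接	64
控	64
推	64
措	64
搏	64
支	65
敏	66
效	66
救	66
教	66
数	66
整	66
收	66
改	66
放	66
故	66
文	67
斗	68
料	68
斤	69
断	69
新	69
斯	69
方	70
旁	70
旋	70
族	70
施	70
无	71
既	71
日	72
星	72
晕	72
时	72
明	72
显	72
早	72
晚	72
昨	72
是	72
晨	72
曰	73
月	74
有	74
期	74
服	74
木	75
染	75
术	75
松	75
林	75
查	75
条	75
柏	75
样	75
根	75
枝	75
机	75
板	75
梅	75
核	75
标	75
树	75
栓	75
械	75
欠	76
次	76
欲	76
欧	76
止	77
正	77
步	77
此	77
歹	78
死	78
残	78
段	79
每	80
母	80
毒	80
比	81
毛	82
毫	82
氏	83
民	83
气	84
氧	84
氟	84
氯	84
氨	84
氢	84
氮	84
水	85
滴	85
注	85
治	85
消	85
沙	85
洛	85
液	85
泻	85
测	85
温	85
海	85
汗	85
洗	85
清	85
淋	85
沉	85
深	85
湿	85
汤	85
泡	85
渐	85
火	86
炎	86
热	86
烧	86
烦	86
然	86
照	86
煎	86
灯	86
点	86
熟	86
爪	87
爬	87
爱	87
父	88
爸	88
片	91
版	91
牙	92
牛	93
物	93
特	93
犬	94
状	94
狂	94
独	94
玄	95
率	95
玉	96
王	96
现	96
理	96
环	96
班	96
瓜	97
瓦	98
瓶	98
甘	99
甜	99
生	100
用	101
田	102
男	102
留	102
疋	103
疏	103
疑	103
疒	104
症	104
疗	104
病	104
痛	104
疹	104
瘙	104
痒	104
疼	104
疾	104
瘤	104
疲	104
疫	104
痰	104
瘀	104
登	105
癸	105
白	106
的	106
百	106
皂	106
皮	107
皿	108
监	108
盐	108
盖	108
盒	108
盘	108
益	108
盛	108
目	109
眠	109
眼	109
看	109
睛	109
直	109
睡	109
盲	109
矛	110
矢	111
知	111
短	111
石	112
矿	112
碎	112
硬	112
碱	112
硫	112
磷	112
码	112
示	113
神	113
祖	113
礼	113
祝	113
福	113
票	113
禁	113
禾	115
科	115
种	115
秒	115
程	115
稳	115
积	115
秋	115
称	115
移	115
穴	116
空	116
穿	116
突	116
立	117
站	117
端	117
章	117
竹	118
第	118
管	118
简	118
等	118
答	118
签	118
箱	118
笑	118
米	119
糖	119
粒	119
粉	119
精	119
类	119
糸	120
给	120
约	120
经	120
缓	120
素	120
红	120
维	120
线	120
结	120
组	120
细	120
级	120
纳	120
紫	120
缶	121
罗	122
置	122
罪	122
署	122
羊	123
美	123
群	123
羽	124
翻	124
翼	124
老	125
者	125
考	125
而	126
耐	126
耗	127
耳	128
联	128
聋	128
聪	128
职	128
肉	130
肺	130
胃	130
肠	130
脉	130
腹	130
胸	130
肿	130
胰	130
肝	130
肾	130
脾	130
胆	130
肌	130
脑	130
脏	130
肤	130
胀	130
育	130
能	130
脱	130
腰	130
脸	130
肥	130
臣	131
卧	131
自	132
至	133
致	133
臼	134
舌	135
舞	136
舟	137
船	137
航	137
般	137
艮	138
良	138
色	139
药	140
莫	140
芬	140
葡	140
萄	140
苦	140
花	140
茶	140
菌	140
苯	140
草	140
蓝	140
蒙	140
蒸	140
虍	141
虑	141
虚	141
虫	142
蚊	142
蛋	142
蜂	142
蛇	142
血	143
行	144
街	144
衡	144
衣	145
补	145
被	145
裂	145
装	145
表	145
西	146
要	146
覆	146
见	147
观	147
规	147
视	147
角	148
解	148
触	148
言	149
诊	149
访	149
词	149
译	149
试	149
话	149
说	149
请	149
误	149
证	149
记	149
讲	149
论	149
议	149
识	149
语	149
谷	150
豆	151
豕	152
象	152
豪	152
贝	154
质	154
负	154
败	154
费	154
贵	154
贫	154
购	154
赤	155
走	156
起	156
超	156
越	156
趋	156
足	157
路	157
跑	157
距	157
跟	157
跳	157
身	158
车	159
转	159
轻	159
输	159
辛	160
辣	160
辨	160
辰	161
辱	161
辵	162
逐	162
道	162
过	162
适	162
进	162
退	162
速	162
通	162
逆	162
造	162
遇	162
运	162
还	162
这	162
边	162
迅	162
邑	163
部	163
那	163
郁	163
都	163
郑	163
酉	164
醇	164
酰	164
酚	164
酒	164
酸	164
配	164
酮	164
酶	164
醒	164
释	165
里	166
量	166
重	166
野	166
金	167
钟	167
钠	167
钙	167
铁	167
银	167
锌	167
针	167
镇	167
错	167
钾	167
长	168
门	169
间	169
闷	169
闭	169
闻	169
问	169
闲	169
阅	169
阜	170
院	170
阿	170
随	170
防	170
降	170
除	170
陈	170
限	170
阵	170
附	170
隶	171
难	172
集	172
雄	172
雌	172
雨	173
露	173
霉	173
雪	173
零	173
需	173
震	173
青	174
静	174
非	175
靠	175
面	176
革	177
鞋	177
韦	178
音	180
页	181
顿	181
顺	181
预	181
领	181
频	181
颈	181
题	181
颤	181
风	182
飞	183
食	184
饭	184
饮	184
饱	184
饿	184
首	185
香	186
马	187
驾	187
骑	187
驱	187
骨	188
高	189
鱼	195
鸟	196
鹿	198
麦	199
麻	200
黄	201
黑	203
鼎	206
鼓	207
鼠	208
鼻	209
齐	210
齿	211
龙	212
龟	213
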