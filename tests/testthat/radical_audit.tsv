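character	kangxi_index
一	1
二	7
人	9
儿	10
入	11
八	12
刀	18
力	19
匕	21
十	24
卜	25
厂	27
又	29
口	30
土	32
士	33
夕	36
大	37
女	38
子	39
寸	41
小	42
尸	44
山	46
川	47
工	48
己	49
巾	50
干	51
幺	52
广	53
弓	57
心	61
戈	62
户	63
手	64
支	65
文	67
斗	68
斤	69
方	70
日	72
曰	73
月	74
木	75
欠	76
止	77
歹	78
比	81
毛	82
氏	83
气	84
水	85
火	86
爪	87
父	88
片	91
牙	92
牛	93
犬	94
玄	95
瓜	97
瓦	98
甘	99
生	100
用	101
田	102
白	106
皮	107
皿	108
目	109
矛	110
矢	111
石	112
示	113
禾	115
穴	116
立	117
竹	118
米	119
缶	121
羊	123
羽	124
老	125
而	126
耳	128
肉	130
臣	131
自	132
至	133
臼	134
舌	135
舟	137
色	139
虫	142
血	143
行	144
衣	145
西	146
角	148
谷	150
豆	151
赤	155
走	156
足	157
身	158
辛	160
辰	161
酉	164
里	166
长	168
青	174
非	175
面	176
革	177
韦	178
音	180
页	181
风	182
飞	183
食	184
首	185
香	186
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
贝	154
车	159
门	169
金	167
马	187
雨	173
见	147
言	149
痛	104
病	104
疹	104
疗	104
药	140
花	140
注	85
液	85
滴	85
治	85
肺	130
胃	130
胸	130
头	37
恶	61
呕	30
吐	30
糖	119
钠	167
针	167
诊	149
院	170
间	169
过	162
道	162
静	174
热	86
炎	86
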