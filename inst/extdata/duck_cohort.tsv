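population	breed	count	type	location	depth_x
wild	Mallard	72	wild	Zhejiang/Ningxia	7.54
local	JinDing duck	11	egg	Longhai, Fujian	6.11
local	Liancheng White duck	3	egg	Liancheng, Fujian	9.74
local	Mawang duck	3	egg	Mawang, Chongqing	9.05
local	Putian Black duck	3	egg	Putian, Fujian	9.78
local	Sansui duck	3	egg	Sansui, Guizhou	8.98
local	Shanma duck	21	egg	Longyan, Fujian	5.47
local	Shaoxing duck	24	egg	Shaoxing, Zhejiang	4.75
local	Taiwan duck	3	egg	Taiwan	9.25
local	Youxian duck	3	egg	You, Hunan	10.19
local	Yulin-Wu duck	9	dual	Yulin, Guangxi	8.64
local	Donglan duck	9	dual	Donglan, Guangxi	8.52
local	Gaoyou duck	11	dual	Gaoyou, Jiangsu	6.24
local	Ji'an Red duck	3	dual	Ji'an, Jiangxi	9.90
local	Longsheng-Cui duck	13	dual	Longsheng, Guangxi	8.86
local	Wenqiao duck	10	dual	Wenqiao, Guangxi	9.27
local	Rongshui-Xiang duck	10	dual	Rongshui, Guangxi	9.66
local	Xilin-Ma duck	10	dual	Xilin, Guangxi	8.87
local	Yulin-Ma duck	10	dual	Yulin, Guangxi	8.85
commercial	Pekin duck	160	meat	Beijing	6.58
commercial	Mapleleaf duck	7	meat	Beijing	4.93
commercial	CherryValley duck	18	meat	Beijing/Zhejiang	4.57
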