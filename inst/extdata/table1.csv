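species,cultivar_name,abbreviation,locality,longitude,latitude,volatile_oil,ether_extract
Z. armatum,Jinyangqing Huajiao,ZA1,Ribu Village Taoping Town Jinyang County Sichuan Province China,103°15′22.372″,27°38′39.763″,7.49,9.77
Z. armatum,Jinyangqing Huajiao,ZA1,Luxiang Village Honglian Town Jinyang County Sichuan Province China,103°9′3.753″,27°35′13.75″,14.16,16.29
Z. armatum,Jinyangqing Huajiao,ZA1,Guangming Village Pailai Town Jinyang County Sichuan Province China,103°8′7.217″,27°34′44.197″,9.99,12.29
Z. armatum,Jinyangqing Huajiao,ZA1,Qingsong Village Jinyang County Sichuan Province China,103°8′8.287″,27°35′20.817″,12.91,11.07
Z. armatum,Tengjiao,ZA2,Zhige Town Hongya County Sichuan Province China,103°15′5.026″,29°55′.564″,10.00,10.12
Z. armatum,Tengjiao,ZA2,Wulong Village Zhige Town Hongya County Sichuan Province China,103°14′30.762″,29°54′55.425″,15.00,11.47
Z. armatum,Tengjiao,ZA2,Doudan Village Beijiao Town Ya'an City Sichuan Province China,102°58′59.941″,29°59′12.439″,13.33,10.39
Z. bungeanum,Yuexigong Jiao,ZB1,Qingsong Village Banqiao Town Yuexi County Sichuan Province China,102°33′32.35″,28°45′20″,6.67,17.07
Z. bungeanum,Yuexigong Jiao,ZB1,Qingsong Village Banqiao Town Yuexi County Sichuan Province China,102°33′32.36″,28°45′21″,7.47,16.92
Z. bungeanum,Yuexigong Jiao,ZB1,Qingsong Village Banqiao Town Yuexi County Sichuan Province China,102°33′34.42″,28°45′25.55″,8.33,15.96
Z. bungeanum,Yuexigong Jiao,ZB1,Qingsong Village Banqiao Town Yuexi County Sichuan Province China,102°33′59.94″,28°45′40.16″,7.50,20.37
Z. bungeanum,Yuexigong Jiao,ZB1,Qingsong Village Banqiao Town Yuexi County Sichuan Province China,102°33′59.22″,28°45′45.75″,6.24,14.43
Z. bungeanum,Yuexigong Jiao,ZB1,Qingsong Village Banqiao Town Yuexi County Sichuan Province China,102°33′58.22″,28°45′44.74″,6.66,20.43
Z. bungeanum,Yuexigong Jiao,ZB1,Hongguang Village Naituo Town Yuexi County Sichuan Province China,102°36′47.95″,28°42′38.35″,5.81,12.43
Z. bungeanum,Yuexigong Jiao,ZB1,Hongguang Village Naituo Town Yuexi County Sichuan Province China,102°36′47.8″,28°42′37.45″,3.33,12.99
Z. bungeanum,Yuexigong Jiao,ZB1,Hongguang Village Naituo Town Yuexi County Sichuan Province China,102°36′46.95″,28°42′35.43″,6.66,13.56
Z. bungeanum,Yuexigong Jiao,ZB1,Ebu Village Gu'er Town Yuexi County Sichuan Province China,102°41′18″,28°25′34″,5.42,14.81
Z. bungeanum,Yuexigong Jiao,ZB1,Ebu Village Gu'er Town Yuexi County Sichuan Province China,102°41′56.76″,28°25′15.32″,4.99,13.00
Z. bungeanum,Yuexigong Jiao,ZB1,Ebu Village Gu'er Town Yuexi County Sichuan Province China,102°41′26.89″,28°25′14.84″,5.00,14.61
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Renyi Village Zeyuan Town Mianning County Sichuan Province China,102°4′53.202″,28°12′21.011″,5.42,11.28
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Songlin Village Manshuiwan Town Mianning County Sichuan Province China,102°10′1.56″,28°12′17.48″,9.16,14.23
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Luba Village Tuowu Town Mianning County Sichuan Province China,102°19′25.227″,28°47′48.82″,5.41,15.47
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Huangjiaba Village Tuowu Town Mianning County Sichuan Province China,102°18′37.257″,28°47′48.82″,8.33,12.15
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Dabaozi Village Caogu Town Mianning County Sichuan Province China,102°14′36″,28°38′21″,6.66,16.00
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Cheyang Village Caogu Town Mianning County Sichuan Province China,102°15′31″,28°40′54″,7.08,11.56
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Jinguang Village Jinping Town Mianning County Sichuan Province China,101°51′29.706″,28°27′19.162″,4.16,11.21
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Jinguang Village Jinping Town Mianning County Sichuan Province China,101°51′1.866″,28°27′44.86″,7.50,16.24
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Jiaoding Village Shaba Town Mianning County Sichuan Province China,102°2′54.348″,28°10′57.063″,7.91,13.62
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Jiaoding Village Shaba Town Mianning County Sichuan Province China,102°2′18.37″,28°11′5.629″,7.50,18.55
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Daqiao Village Daqiao Town Mianning County Sichuan Province China,102°13′49.437″,28°42′1.894″,3.33,11.03
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Dayanjing Village Wuhai Mianning Sichuan Province China,102°15′38″,28°43′37″,3.75,16.77
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Shigu Village Huilong Town Mianning County Sichuan Province China,102°07′32.1″,28°28′47.5″,7.49,13.26
Z. bungeanum,Lingshang Zhenglujiao,ZB2,Tianba Village Tianba Luding County Sichuan Province China,102°14′17.02″,29°54′2.358″,2.50,12.22
Z. bungeanum,Da Hongpao,ZB3,Shuitang Village Zhenping Town Songpan County Sichuan Province China,103°45′53.575″,32°13′9.126″,7.08,12.56
Z. bungeanum,Da Hongpao,ZB3,Shuitang Village Zhenping Town Songpan County Sichuan Province China,103°46′57′,32°13′14′,5.41,9.71
Z. bungeanum,Da Hongpao,ZB3,Suoqiao Village Yanmen Town Wenchuan County Sichuan Province China,103°37′41.669″,31°28′52.577″,4.58,12.85
Z. bungeanum,Da Hongpao,ZB3,Xinmin Village Zhenping Town Songpan County Sichuan Province China,103°52′5.77″,32°14′6.519″,5.42,10.40
Z. bungeanum,Da Hongpao,ZB3,Xinmin Village Zhenping Town Songpan County Sichuan Province China,103°52′32.539″,32°13′44.033″,5.41,10.47
Z. bungeanum,Da Hongpao,ZB3,Mayizu Town Jinyang County Sichuan Province China,103°17′1.154″,27°41′4.056″,6.25,15.98
Z. bungeanum,Da Hongpao,ZB3,Taiping Village Taiping Town Mao County Sichuan Province China,103°40′41.77″,32°1′17.501″,5.83,10.95
Z. bungeanum,Hanyuan Huajiao,ZB4,Xinli Village Qingxi Town Hanyuan County Sichuan Province China,102°35′12.155″,29°34′59.343″,3.33,13.05
Z. bungeanum,Hanyuan Huajiao,ZB4,Xinli Village Qingxi Town Hanyuan County Sichuan Province China,102°37′34″,29°36′02″,13.33,14.98
Z. bungeanum,Hanyuan Huajiao,ZB4,Shuangping Village Qingxi Town Hanyuan County Sichuan Province,102°36′44.682″,29°35′49.286″,6.66,9.94
Z. bungeanum,Hanyuan Huajiao,ZB4,Guanhua Village Yidong Town Hanyuan County Sichuan Province China,102°26′11.65″,29°41′10.727″,6.25,15.50
Z. bungeanum,Hanyuan Huajiao,ZB4,Guanhua Village Yidong Town Hanyuan County Sichuan Province China,102°26′13.792″,29°41′9.657″,7.50,18.23
Z. bungeanum,Hanyuan Huajiao,ZB4,Dadi Village Liyuan Town Hanyuan County Sichuan Province China,102°24′53″,29°35′19″,10.83,20.16
Z. bungeanum,Hanyuan Huajiao,ZB4,Gaoqiao Village Sanjiao Yidong Town Hanyuan County Sichuan Province China,102°24′37″,29°41′64″,10.42,14.23
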