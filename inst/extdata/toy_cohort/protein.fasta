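>G0001
MHYSVSLASFRFAPVLRLTYKGHRANEPLYLVTEGHCITRVGSRFGVSALDPLYSPIDDSLNVTREYLILRADRALARDI
KALHHPETPLSLELGLQALLSTRYALERSSLDRWRNVCQDLWITDGRTLSFLRTRVTRQLRRAIRTKDDAVTTIIIWRSD
YQGSFCGSWSMLTEAEYCCFVMILTWAGYHAMPVALLRHPNRSHVASGVGVLFIKLLRVIHAMHLHGIVGRQISPWPVKG
IGLRDVTAQPDLPCEHRSTITDITLGLYLAPVSLYLGFRKKATGPVLFCRALILTSNGRLAIEA
>G0002
MHLPDCAPERTRPIPRPASVACVCNLLIRVRPSVMQWTSTTIMHHKGSAGSDTLHLLVSSSGLQALARPVWRSIQWSIPF
RTSRIRSYSNTIKAAKFRRAESPNGCEVRSLLRQNKSNTMSRTLINHPRHLKHLFTQAPLWAQGAHFGTAQRCVRTQDCL
SFVSQLGYAPHIVGSRKSSPCCIRGATYPCPSYTTSSRTCRGGTQMEWRWHVSYSLLTSPLGSPTVPSKVKYLRVPLQSQ
RLSVEFVWHGVVMQRPDGTSLTNFIQSILMLRQTHNCQLRTSGRS
>G0003
MSSYRTYDRFTRVEYRPIEDCLRCACSLIEAHSSSQIRGTLLAQIRSFPPPVSGTMPPEFEVICLRSAWPLAAPIGYTFS
WAPVPLRLAIAIAASRGAPVKRLPSRFPLTRNDWNYQPWTPHPYVLNTELKSVALGLSSPYFSQTLPMHGYCCRAVRYKR
SDHSRGRRRHDAHHLVSIPTYLLRPKAALCKIMHKETRHRCVPYNIHFKRLIQSIRGTTHSYAIRNYCPKTPANIPSIDG
TRLHRRLVSIRDLTGASPAVYSSQSNVEADYKLARMWDGVTARTLGRRTSTKIVDESSGVGSDQIQLRNSSRPFCNKRCT
RVNCRREPAFFLYRSTDKDYASMVPVPLARHGRKVDVMFIITLSTQLLSR
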