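>brvh_synthetic_standin synthetic stand-in protein, 509 aa (1530 bp CDS); GxGxxG 16-21, K83, WxWxIP 275-280, E349
MEQVWAEISQFYHVGGDGYSGSKTLPLLLPELPTLDYLKANPWEALRSANLTLDVRDESR
GDDGMNRTGYAERGRTVKLAPAKGNLTSSFISNGDAVLLPARVTEAVAFPVTFFQRDSAN
PEGPLGPDPAGCQPLLRALALKTDKKGDSHEARSALMLDPYGQEDIGLQRDLLKQGQEKL
LTAIIAGENRYTLWHCPLFPNNSSPEPSESPGEVRFLLSDKLQVDMTDGRIYLNVYGYTS
YEQDHKAVQPVASQKQTYIYGQHFLNDELPTDCSWVWGIPELFSSLAERSGEMEGYKADI
ERLGSDMDAYILGSQFTANLETDIRPWTELNHNTSLNVNDEVVGSLDLELIWGVLYIREV
DTNYGTVHIVSAHSVVHFKCAQPEEAAVLTAYAVPHEKNTTAPSPDNYCLPQPAPETEAK
FPVTKLDPEFENSDPYENMYIEPSCEFLVAGAVTVRSQEFAEHQVSSSPINLKVDKPLEC
SIVHRFWLCFFTKSQKTIMNDIINTERPI
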