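species_group,species,authority,endemic,exotic,status,exclusion_reason,type_lat,type_lon,comments
angulinode,smithi,"Mayr, 1879",no,no,valid,,,,
bicarinatum,bicarinatum,"(Nylander, 1846)",no,no,valid,,,,"Cosmopolitan tramp; native range likely Southeast Asia, exotic status in India unresolved (flag follows checklist)"
bicarinatum,indicum,"Forel, 1913",no,no,valid,,,,
bicarinatum,pacificum,"Mayr, 1870",no,no,valid,,,,"Native range unknown; exotic classification problematic, flag follows checklist"
bicarinatum,petiolatum,"Sheela & Narendran, 1998",yes,no,valid,,,,"Identity doubtful; types unavailable"
bicarinatum,scabrum,"Mayr, 1879",no,no,valid,,,,
caespitum,nursei,"Bingham, 1903",no,no,valid,,,,"Only Palearctic element; Kerala record extremely dubious"
ciliatum,shivalikense,"Bharti & Kumar, 2012",yes,no,valid,,,,
fergusoni,fergusoni,"Forel, 1902",yes,no,valid,,,,
inglebyi,elisabethae,"Forel, 1904",yes,no,valid,,,,
inglebyi,inglebyi,"Forel, 1902",yes,no,valid,,,,"Dubious records from Borneo and China (Yunnan)"
inglebyi,myops,"Bolton, 1977",yes,no,valid,,,,
inglebyi,triangulatum,"Bharti & Kumar, 2012",yes,no,valid,,,,
inglebyi,jarawa,,yes,no,valid,,11.975817,93.016897,"New species; Havelock Island, Andaman Islands"
melleum,mayri,"(Forel, 1912)",no,no,valid,,,,
melleum,wroughtoni,"(Forel, 1902)",no,no,valid,,,,"Likely a complex of cryptic species"
mixtum,malabarense,"Sheela & Narendran, 1998",yes,no,valid,,,,
mixtum,mixtum,"Forel, 1902",yes,no,valid,,,,"Record from Borneo dubious"
mixtum,rugigaster,"Bolton, 1977",yes,no,valid,,,,
mixtum,sentosum,"Sheela & Narendran, 1998",yes,no,valid,,,,
obesum,coonoorense,"Forel, 1902",yes,no,valid,,,,
obesum,decamerum,"(Forel, 1902)",yes,no,valid,,,,
obesum,lanuginosum,"Mayr, 1870",no,no,valid,,,,
obesum,obesum,"Andre, 1887",no,no,valid,,,,
obesum,rossi,"(Bolton, 1976)",yes,no,valid,,,,
simillimum,caldarium,"(Roger, 1857)",no,yes,valid,,,,"Panglobal tramp of Afrotropical origin"
simillimum,simillimum,"(Smith, 1851)",no,yes,valid,,,,"Panglobal tramp of Afrotropical origin"
tonganum,barryi,"Mathew, 1981",yes,no,valid,,,,
tonganum,christiei,"Forel, 1902",yes,no,valid,,,,
tonganum,salvatum,"Forel, 1902",yes,no,valid,,,,
tonganum,krishnani,,yes,no,valid,,12.003499,92.993196,"New species; Havelock Island, Andaman Islands"
tortuosum,belgaense,"Forel, 1902",yes,no,valid,,,,
tortuosum,keralense,"Sheela & Narendran, 1998",yes,no,valid,,,,
tortuosum,pilosum,"Emery, 1893",yes,no,valid,,,,"Record from Zhejiang dubious"
tortuosum,urbanii,"Bolton, 1977",yes,no,valid,,,,
tortuosum,tortuosum,"Roger, 1863",no,no,valid,,,,
tortuosum,yerburyi,"Forel, 1902",yes,no,valid,,,,"Record from Yunnan dubious"
walshi,cordatum,"Sheela & Narendran, 1998",yes,no,valid,,,,
walshi,kheperra,"(Bolton, 1976)",no,no,valid,,,,
walshi,walshi,"(Forel, 1890)",no,no,valid,,,,
unclear,beesoni,"(Mukerjee, 1934)",yes,no,valid,,,,"Initially described in Myrmica; species group unknown"
unclear,meghalayense,"Bharti, 2011",yes,no,valid,,,,"Originally placed in bicarinatum group; placement dubious, treated as unclear"
tonganum,tonganum,"Mayr, 1870",no,no,excluded,"Indian records based on a misidentification; the material reported under this name is T. salvatum",,,"Widespread in tropical Asia; retained in the tonganum-group key to facilitate future identifications"
unclear,browni,"Mathew & Tiwari, 2000",no,no,excluded,"Junior primary homonym of T. browni Bolton 1980; replaced by T. meghalayense Bharti 2011",,,
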