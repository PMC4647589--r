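(('Colletes cunicularius':1,('Lasioglossum malachurum':1,'Lasioglossum zephyrum':1):1):1,(('Osmia rufa':1,'Megachile rotundata':1):1,('Amegilla dawsoni':1,('Centris analis':1,('Apis mellifera':1,(('Bombus terrestris':1,('Bombus impatiens':1,'Bombus hypnorum':1):1):1,(('Melipona bicolor':1,'Melipona scutellaris':1):1,('Scaptotrigona depilis':1,('Friesella schrottkyi':1,'Schwarziana quadripunctata':1):1):1):1):1):1):1):1):1);
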