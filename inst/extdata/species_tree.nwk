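(hagfishes,(lampreys,(sharks,((holostei,teleostei)neopterygii,(coelacanth,(frogs,(mammals,(turtles_crocodiles,birds)archosauria)amniota)tetrapoda)sarcopterygii)osteichthyes)gnathostomata)vertebrata)craniata;
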