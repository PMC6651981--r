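name,type,c2_pg,variant1,variant2
Baby Blue,M,4.4,B1,B1
Bela,M,6.5,B1,B1
Benelux,M,8.9,B1,B1
Bodensee II,M,4.4,B1,B1
Choco Bleu,M,4.5,B1,B1
Diva fiore,M,4.6,B1,B1
Glaernisch,M,4.4,B1,B1
Nikko Blue I,M,4.5,B1,B1
Paris Rampp,M,4.4,B1,B1
Pfau II,M,4.4,B1,B1
R. F. Felton,M,7.0,B1,B1
Renate Steiniger I,M,4.4,B1,B1
Toedi,M,4.5,B1,B1
unknown 1,M,4.4,B1,B1
unknown 3,M,6.6,B1,B1
unknown 4,M,6.6,B1,B1
unknown 7,M,4.4,B1,B1
unknown 8,M,4.5,B1,B1
unknown 12,M,6.7,B1,B1
Early Blue,M,,B2,B2
Forever Pink,M,4.6,B2,B2
Hoernli,M,4.5,B2,B2
Madame Emile Mouillere,M,4.5,B2,B2
Marisii Perfecta,L,4.5,B2,B2
Mathilde Guetges I,M,4.4,B2,B2
Sheila,L,4.4,B2,B2
Sir Joseph Banks,M,,B2,B2
unknown 2,M,4.4,B2,B2
unknown 5,M,6.7,B2,B2
Bergfink,L,6.7,B3,B3
Buchfink,L,6.7,B3,B3
Buntspecht,L,4.4,B3,B3
Rotschwanz I,L,4.5,B3,B3
Rotschwanz II,L,4.4,B3,B3
Zeisig,L,4.4,B3,B3
Bachstelze,L,4.3,B4,B4
Gimpel,L,4.4,B4,B4
Libelle,L,4.4,B4,B4
Mariesii Lilacina,L,4.2,B5,B5
Nikko Blue II,L,4.0,B5,B5
Mariesii Grandiflora,L,4.3,B6,B6
Veitchii,L,4.2,B6,B6
Blaukehlchen,L,4.5,B1,B3
Blaumeise,L,6.5,B1,B3
Dark Angel,L,4.5,B1,B3
Eisvogel,L,6.6,B1,B3
Grasmuecke,L,4.4,B1,B3
Little Prince,L,4.4,B1,B3
Moewe,L,6.6,B1,B3
Nachtigall,L,6.5,B1,B3
Rotkehlchen,L,4.5,B1,B3
Blaeuling,L,4.5,B1,B4
Geoffrey Chadbund,L,4.4,B1,B4
Mak20,L,,B1,B4
Sweet Dreams,L,4.5,B1,B4
Zaunkoenig,L,4.4,B3,B4
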