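taxon	species	site	care_state
A_leptura_1	Asprotilapia leptura	Isanga	Biparental Mouthbrooder
A_leptura_2	Asprotilapia leptura	Isanga	Biparental Mouthbrooder
A_leptura_3	Asprotilapia leptura	Tongwa	Biparental Mouthbrooder
C_macrops_1	Callochromis macrops	Ndole	Maternal Mouthbrooder
C_stappersii_1	Callochromis stappersii	Aquarium Trade	Maternal Mouthbrooder
C_furcifer_1	Cyathopharynx furcifer	Toby's lodge	Maternal Mouthbrooder
E_melanogenys_1	Enantiopus melanogenys	Aquarium Trade	Maternal Mouthbrooder
E_melanogenys_2	Enantiopus melanogenys	Aquarium Trade	Maternal Mouthbrooder
E_melanogenys_3	Enantiopus melanogenys	Aquarium Trade	Maternal Mouthbrooder
M_tenuidentata_1	Microdontochromis tenuidentata	Mpulungu	Maternal Mouthbrooder
M_tenuidentata_2	Microdontochromis tenuidentata	Mpulungu	Maternal Mouthbrooder
M_tenuidentata_3	Microdontochromis tenuidentata	Mpulungu	Maternal Mouthbrooder
O_nasuta_1	Ophthalmotilapia nasuta	Nakaku	Maternal Mouthbrooder
O_ventralis_1	Ophthalmotilapia ventralis	Wonzye	Maternal Mouthbrooder
X_bathyphila_1	Xenotilapia bathyphila	Mbita Island West	Maternal Mouthbrooder
X_boulengeri_1	Xenotilapia boulengeri	Chimba	Biparental Mouthbrooder
X_boulengeri_2	Xenotilapia boulengeri	Kalambo Lodge	Biparental Mouthbrooder
X_flavipinnis_1	Xenotilapia flavipinnis	Kantalamba	Biparental Mouthbrooder
X_flavipinnis_2	Xenotilapia flavipinnis	Aquarium Trade	Biparental Mouthbrooder
X_flavipinnis_3	Xenotilapia flavipinnis	Katete	Biparental Mouthbrooder
X_flavipinnis_4	Xenotilapia flavipinnis	Kigoma	Biparental Mouthbrooder
X_ochrogenys_1	Xenotilapia ochrogenys	Kavalla, Congo	Maternal Mouthbrooder
X_ochrogenys_2	Xenotilapia ochrogenys	Kavalla, Congo	Maternal Mouthbrooder
X_ochrogenys_3	Xenotilapia ochrogenys	Kavalla, Congo	Maternal Mouthbrooder
X_ornatipinnis_1	Xenotilapia ornatipinnis	Aquarium Trade	Maternal Mouthbrooder
X_ornatipinnis_2	Xenotilapia ornatipinnis	Aquarium Trade	Maternal Mouthbrooder
X_sima_1	Xenotilapia sima	Aquarium Trade	Maternal Mouthbrooder
X_sima_2	Xenotilapia sima	Aquarium Trade	Maternal Mouthbrooder
X_papilio_1	Xenotilapia sp. "papilio sunflower"	Chituta Bay	Biparental Mouthbrooder
X_papilio_2	Xenotilapia sp. "papilio sunflower"	Chituta Bay	Biparental Mouthbrooder
X_papilio_3	Xenotilapia sp. "papilio sunflower"	Aquarium Trade	Biparental Mouthbrooder
X_papilio_4	Xenotilapia sp. "papilio sunflower"	Aquarium Trade	Biparental Mouthbrooder
X_spiloptera_1	Xenotilapia spiloptera	Kapembwa	Biparental Mouthbrooder
X_spiloptera_2	Xenotilapia spiloptera	Chimba	Biparental Mouthbrooder
X_spiloptera_3	Xenotilapia spiloptera	Mbita Island East	Biparental Mouthbrooder
X_spiloptera_4	Xenotilapia spiloptera	Kigoma	Biparental Mouthbrooder
X_spiloptera_5	Xenotilapia spiloptera	Kigoma	Biparental Mouthbrooder
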