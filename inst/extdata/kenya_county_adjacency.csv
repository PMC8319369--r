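# Approximate queen contiguity (shared border or corner) between Kenya's 47
# counties, hand-curated from a reference map. Intended as a test and
# demonstration fixture; minor border discrepancies are possible and any
# user-supplied edge list is accepted by build_region_graph().
region_id_a,region_id_b
mombasa,kwale
mombasa,kilifi
kwale,kilifi
kwale,taita_taveta
kilifi,tana_river
kilifi,taita_taveta
tana_river,lamu
tana_river,garissa
tana_river,kitui
tana_river,isiolo
tana_river,taita_taveta
lamu,garissa
taita_taveta,kitui
taita_taveta,makueni
taita_taveta,kajiado
garissa,wajir
garissa,isiolo
wajir,mandera
wajir,isiolo
wajir,marsabit
marsabit,turkana
marsabit,samburu
marsabit,isiolo
isiolo,samburu
isiolo,laikipia
isiolo,meru
meru,tharaka_nithi
meru,nyeri
meru,laikipia
tharaka_nithi,embu
tharaka_nithi,kitui
embu,kirinyaga
embu,kitui
embu,machakos
embu,muranga
kitui,machakos
kitui,makueni
machakos,makueni
machakos,kajiado
machakos,nairobi
machakos,kiambu
machakos,muranga
makueni,kajiado
nairobi,kiambu
nairobi,kajiado
kiambu,muranga
kiambu,nyandarua
kiambu,nakuru
kiambu,kajiado
muranga,kirinyaga
muranga,nyeri
muranga,nyandarua
kirinyaga,nyeri
nyeri,nyandarua
nyeri,laikipia
nyandarua,nakuru
nyandarua,laikipia
laikipia,samburu
laikipia,baringo
laikipia,nakuru
samburu,turkana
samburu,baringo
turkana,baringo
turkana,west_pokot
west_pokot,baringo
west_pokot,elgeyo_marakwet
west_pokot,trans_nzoia
trans_nzoia,elgeyo_marakwet
trans_nzoia,uasin_gishu
trans_nzoia,bungoma
trans_nzoia,kakamega
elgeyo_marakwet,baringo
elgeyo_marakwet,uasin_gishu
uasin_gishu,baringo
uasin_gishu,nandi
uasin_gishu,kakamega
uasin_gishu,kericho
nandi,kakamega
nandi,vihiga
nandi,kisumu
nandi,kericho
baringo,nakuru
nakuru,narok
nakuru,kericho
nakuru,bomet
nakuru,kajiado
narok,kajiado
narok,bomet
narok,kisii
narok,migori
kericho,bomet
kericho,nyamira
kericho,kisumu
bomet,nyamira
nyamira,kisii
nyamira,homa_bay
kisii,migori
kisii,homa_bay
migori,homa_bay
homa_bay,kisumu
kisumu,vihiga
kisumu,siaya
siaya,busia
siaya,kakamega
vihiga,kakamega
kakamega,bungoma
kakamega,busia
bungoma,busia
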