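# Kenya counties (post-2013 devolution) grouped by former province.
# country_code: ISO 3166-1 alpha-2.
region_id,province_id,country_code
mombasa,coast,KE
kwale,coast,KE
kilifi,coast,KE
tana_river,coast,KE
lamu,coast,KE
taita_taveta,coast,KE
garissa,north_eastern,KE
wajir,north_eastern,KE
mandera,north_eastern,KE
marsabit,eastern,KE
isiolo,eastern,KE
meru,eastern,KE
tharaka_nithi,eastern,KE
embu,eastern,KE
kitui,eastern,KE
machakos,eastern,KE
makueni,eastern,KE
nyandarua,central,KE
nyeri,central,KE
kirinyaga,central,KE
muranga,central,KE
kiambu,central,KE
turkana,rift_valley,KE
west_pokot,rift_valley,KE
samburu,rift_valley,KE
trans_nzoia,rift_valley,KE
uasin_gishu,rift_valley,KE
elgeyo_marakwet,rift_valley,KE
nandi,rift_valley,KE
baringo,rift_valley,KE
laikipia,rift_valley,KE
nakuru,rift_valley,KE
narok,rift_valley,KE
kajiado,rift_valley,KE
kericho,rift_valley,KE
bomet,rift_valley,KE
kakamega,western,KE
vihiga,western,KE
bungoma,western,KE
busia,western,KE
siaya,nyanza,KE
kisumu,nyanza,KE
homa_bay,nyanza,KE
migori,nyanza,KE
kisii,nyanza,KE
nyamira,nyanza,KE
nairobi,nairobi,KE
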