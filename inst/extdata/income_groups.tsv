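# World Bank country income classification. fiscal-year: FY2022
# Columns: name (country name or alias), income_group (high / upper-middle /
# lower-middle / low), canonical (primary name for alias rows, empty
# otherwise). User-replaceable via read_income_table() to pin another
# fiscal year.
name	income_group	canonical
Australia	high
United States	high
USA	high	United States
U.S.A	high	United States
United States of America	high	United States
United Kingdom	high
UK	high	United Kingdom
U.K	high	United Kingdom
England	high	United Kingdom
Scotland	high	United Kingdom
Wales	high	United Kingdom
Northern Ireland	high	United Kingdom
Canada	high
Germany	high
France	high
Netherlands	high
The Netherlands	high	Netherlands
Sweden	high
Norway	high
Denmark	high
Finland	high
Iceland	high
Switzerland	high
Austria	high
Belgium	high
Luxembourg	high
Ireland	high
Italy	high
Spain	high
Portugal	high
Greece	high
Japan	high
South Korea	high
Republic of Korea	high	South Korea
Korea	high	South Korea
Taiwan	high
Hong Kong	high
Singapore	high
Israel	high
New Zealand	high
Saudi Arabia	high
United Arab Emirates	high
UAE	high	United Arab Emirates
Qatar	high
Kuwait	high
Chile	high
Uruguay	high
Poland	high
Czech Republic	high
Czechia	high	Czech Republic
Hungary	high
Croatia	high
Slovakia	high
Slovenia	high
Estonia	high
Latvia	high
Lithuania	high
China	upper-middle
People's Republic of China	upper-middle	China
Brazil	upper-middle
Mexico	upper-middle
Russia	upper-middle
Russian Federation	upper-middle	Russia
Turkey	upper-middle
South Africa	upper-middle
Colombia	upper-middle
Peru	upper-middle
Ecuador	upper-middle
Argentina	upper-middle
Thailand	upper-middle
Malaysia	upper-middle
Bulgaria	upper-middle
Romania	upper-middle
Serbia	upper-middle
Belarus	upper-middle
Cuba	upper-middle
Jamaica	upper-middle
Iraq	upper-middle
Jordan	upper-middle
Lebanon	upper-middle
Botswana	upper-middle
Namibia	upper-middle
Fiji	upper-middle
India	lower-middle
Pakistan	lower-middle
Bangladesh	lower-middle
Nepal	lower-middle
Sri Lanka	lower-middle
Myanmar	lower-middle
Cambodia	lower-middle
Indonesia	lower-middle
Philippines	lower-middle
Vietnam	lower-middle
Viet Nam	lower-middle	Vietnam
Nigeria	lower-middle
Kenya	lower-middle
Ghana	lower-middle
Senegal	lower-middle
Cameroon	lower-middle
Ivory Coast	lower-middle
Cote d'Ivoire	lower-middle	Ivory Coast
Tanzania	lower-middle
Zimbabwe	lower-middle
Egypt	lower-middle
Morocco	lower-middle
Tunisia	lower-middle
Ukraine	lower-middle
Bolivia	lower-middle
Haiti	lower-middle
Iran	lower-middle
Islamic Republic of Iran	lower-middle	Iran
Papua New Guinea	lower-middle
Zambia	low
Malawi	low
Ethiopia	low
Uganda	low
Mozambique	low
Rwanda	low
Burundi	low
Mali	low
Niger	low
Chad	low
Somalia	low
Sudan	low
South Sudan	low
Democratic Republic of the Congo	low
DR Congo	low	Democratic Republic of the Congo
Afghanistan	low
Yemen	low
Syria	low
Syrian Arab Republic	low	Syria
Eritrea	low
Madagascar	low
Sierra Leone	low
Liberia	low
The Gambia	low
Gambia	low	The Gambia
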