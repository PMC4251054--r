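Afghanistan
Argentina
Australia
Austria
Bangladesh
Belgium
Brazil
Bulgaria
Canada
Chile
China
Colombia
Croatia
Cuba
Czech Republic
Denmark
Egypt
England
Estonia
Ethiopia
Finland
France
Germany
Ghana
Greece
Hungary
Iceland
India
Indonesia
Iran
Iraq
Ireland
Israel
Italy
Japan
Jordan
Kenya
Korea
Kuwait
Latvia
Lebanon
Lithuania
Luxembourg
Malaysia
Mexico
Morocco
Nepal
Netherlands
New Zealand
Nigeria
Norway
Pakistan
Peru
Philippines
Poland
Portugal
Qatar
Romania
Russia
Saudi Arabia
Scotland
Serbia
Singapore
Slovakia
Slovenia
South Africa
Spain
Sri Lanka
Sweden
Switzerland
Taiwan
Thailand
Tunisia
Turkey
Uganda
Ukraine
United Arab Emirates
United Kingdom
Uruguay
Venezuela
Vietnam
Wales
Zimbabwe
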