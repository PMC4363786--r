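symptom_id	description	female_only
PS1	Feeling hot in palms or soles but cool in body	FALSE
PS2	Sweating when sleeping but not after waking up	FALSE
PS3	Feeling hot off and on, especially in midnight or at afternoon	FALSE
PS4	Feeling dry in mouth and throat lately	FALSE
PS5	Feeling limply and exhausted	FALSE
PS6	Feeling short of breath, especially after sports	FALSE
PS7	Sweating a lot by day, especially after sports	FALSE
PS8	Feeling tired in spirit, lazy, and wordless	FALSE
PS9	Having blurred vision and feeling dry in eyes	FALSE
PS10	Feeling nervous and having super abundance of dreams	FALSE
PS11	Having hair thin and dry and easily falling out	FALSE
PS12	Ever feeling numb in your hands, feet, and body	FALSE
PS13	(Female) the menses being little in quantity and light in color	TRUE
PS14	Feeling depressed	FALSE
PS15	Feeling tight in chest and like long out of breath	FALSE
PS16	Feeling swelling pain in lateral thorax	FALSE
PS17	Feeling obstructive in epigastrium and indigestive after taking food	FALSE
PS18	Feeling swelling pain in stomach even in hypogastrium or costal region	FALSE
PS19	Feeling pain like prodding in a certain part of the body	FALSE
PS20	Having suggillation in your skins	FALSE
PS21	Having a sclerotic lump detected in body	FALSE
PS22	(Female) the menses being dark purple in color or with some blood clots	TRUE
PS23	Coughing up dense phlegm	FALSE
PS24	Feeling nauseous and wanting to vomit	FALSE
PS25	Feeling heavy and dazed in head	FALSE
PS26	Feeling dizzy and fainty	FALSE
PS27	Feeling obstructive in chest or gastric cavity	FALSE
PS28	Having smooth lumps in some organ of your body	FALSE
PS29	Feeling febrile in your body, especially in chest and stomach	FALSE
PS30	Being impatient and irritable	FALSE
PS31	Ever feeling bitter taste in mouth	FALSE
PS32	Having mouth or tongue ulcerated	FALSE
PS33	Having gingiva gall	FALSE
PS34	Usually feeling thirsty and wanting to drink something cold	FALSE
PS35	Having constipation	FALSE
PS36	Having urine little in quantity and yellow in color	FALSE
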