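name	breed	reads	snps	bases_per_snp	sex
Pixel	Burmese	331813	174212	524	F
Zeelie	Persian	298332	174706	510	F
Tipper	Cornish Rex	272607	164054	503	M
Scooter	Ragdoll	298409	168455	510	M
Speedy	Domestic Shorthair	310364	158148	569	F
Cocoa	Siamese	293712	152984	516	F
Nancy	African wild cat	1373060	938386	360	F
Cinnamon	Abyssinian	8186934	1323794	1520	F
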