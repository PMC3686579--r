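name	predator_species	sequence	three_prime_block
blkNsav	Nectamia savayensis	CAAAGAATCAGAATAGGTGTTGGTAAAGA	TRUE
blkMber	Myripristis berndti	CAAAGAATCAGAACAGGTGTTGATAAAGG	TRUE
blkSmic	Sargocentron microstoma	CAAAGAATCAGAATAGGTGTTGATAAAGA	TRUE
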