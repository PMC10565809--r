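polymer_id,drug_id,polymer_feed_gL,drug_feed_gL,solubilized_gL,day,medium
pPrOx,BT44,10,2,0.05,0,water
pPrOx,BT44,10,4,0.05,0,water
pPrOx,BT44,10,6,0.05,0,water
pPrOx,BT44,10,8,0.05,0,water
pPrOx,BT44,10,10,0.05,0,water
pBuOx,BT44,10,2,0.70,0,water
pBuOx,BT44,10,4,1.10,0,water
pBuOx,BT44,10,6,1.40,0,water
pBuOx,BT44,10,8,2.40,0,water
pBuOx,BT44,10,10,1.50,0,water
pPentOx,BT44,10,2,1.70,0,water
pPentOx,BT44,10,4,3.40,0,water
pPentOx,BT44,10,6,5.10,0,water
pPentOx,BT44,10,8,6.80,0,water
pPentOx,BT44,10,10,9.00,0,water
pPentOx,BT44,100,20,19.30,0,water
pBuOx,BT44,10,8,2.00,1,water
pBuOx,BT44,10,8,1.20,5,water
pBuOx,BT44,10,8,0.75,15,water
pPentOx,BT44,10,2,0.00,1,water
pPentOx,BT44,10,2,0.00,5,water
pPentOx,BT44,10,2,0.00,15,water
pPentOx,BT44,10,10,8.50,1,water
pPentOx,BT44,10,10,4.00,5,water
pPentOx,BT44,10,10,0.00,15,water
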