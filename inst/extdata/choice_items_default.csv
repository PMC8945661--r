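item_id,ss_amount,ll_amount,delay_days
item1,840,2311,4
item2,1300,3000,15
item3,1800,4000,40
item4,2300,5000,100
item5,2800,6000,250
item6,3300,7000,500
item7,3990,8190,939
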