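policy_id,class,direction,combination
bc_dealer,background_checks,restrictive,purchase_possession
bc_private,background_checks,restrictive,purchase_possession
possess_under18,minimum_age,restrictive,purchase_possession
purchase_under20,minimum_age,restrictive,purchase_possession
wait_24h,waiting_period,restrictive,purchase_possession
wait_7day,waiting_period,restrictive,purchase_possession
cap_storage,child_access,restrictive,use_storage
shall_issue,concealed_carry,permissive,use_storage
permitless_carry,concealed_carry,permissive,use_storage
stand_your_ground,stand_your_ground,permissive,use_storage
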