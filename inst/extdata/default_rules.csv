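level,label,action
any,spices,ZERO
any,herbs,ZERO
any,fats and oils,ZERO
any,plain cereals,ZERO
any,plain cereal grains,ZERO
any,pastas,ZERO
any,rice,ZERO
any,flours,ZERO
any,eggs,ZERO
any,eggs and egg products,ZERO
any,fruits,ZERO
any,fresh fruit,ZERO
any,vegetables,ZERO
any,green leafy and yellow vegetables,ZERO
any,legumes,ZERO
any,fresh fish and meat,ZERO
any,fresh meat,ZERO
any,fresh seafood,ZERO
any,organ meat,ZERO
any,non-sweetened beverages,ZERO
any,coffee,ZERO
any,tea,ZERO
any,plain milk,ZERO
any,whole milk,ZERO
any,alcoholic beverages,ZERO
any,non-sugar-sweetened dairy products,ZERO
any,nuts coconut and seeds,ZERO
any,dried beans nuts and seeds,ZERO
any,plain breads,ZERO
any,crackers,ZERO
any,tubers,ZERO
any,starchy roots and tubers,ZERO
any,vinegar,ZERO
any,infant formula,ZERO
any,sugars and syrups,FULL
any,confectionery,FULL
any,non-dairy confectionery,FULL
any,breakfast cereals,FULL
any,cereal bars,FULL
any,coffee and beverage base with no milk,FULL
any,crumbed battered meat and seafood,FULL
any,processed meat,FULL
any,sweetened beverages,FULL
any,soft drinks,FULL
any,sport drinks,FULL
any,flavored water,FULL
any,cookies,FULL
any,biscuits,FULL
any,cakes,FULL
any,donuts,FULL
any,soy beverages,FULL
any,soy yoghurt,FULL
any,fruit juices,FULL
any,honey,FULL
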