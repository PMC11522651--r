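# Packaged phrase pool for the deterministic mock backend and the synthetic
# bank generator. Generic adherence-reminder phrasing written for this
# package; GSM-7-safe, simple wording so readability metrics are computable.
# Lines starting with '#' are section markers or comments.
Taking your dose at the same time each day builds a strong habit.
A quick note in your day can keep your plan on track.
Set a phone cue so your next dose is easy to recall.
Keep your pills where you can see them each morning.
Your health team is proud of each day you stay on plan.
Pair your dose with a daily task like brushing your teeth.
One small step each day adds up to big gains for your health.
A pill box with day labels makes the week easy to manage.
If a dose is hard to recall, tie it to your morning meal.
Tell a friend about your plan so they can cheer you on.
Each dose you take today helps you feel your best tomorrow.
Check your supply this week so you can refill in good time.
You have done this before and you can do it again today.
A short walk after your dose can make the habit stick.
Write down how you feel on days when you stay on plan.
Good work this week; keep your streak going one day at a time.
Your plan is yours; shape it so it fits your daily life.
When travel breaks your routine, pack your doses the night before.
Ask your pharmacist about simple ways to track each dose.
Celebrate each full week on plan with something you enjoy.
Notice the extra energy you have when you stay on schedule.
Place a note on the fridge as a friendly daily nudge.
Your future self will thank you for the care you take today.
Missing one dose happens; just pick the plan back up today.
Keep water by your bed so the morning dose is simple.
A steady routine now means fewer worries down the road.
Share your wins with family; support makes habits last.
Think back to your best week and repeat what worked then.
# simple-words
take your dose now each day at the same time keep it near your bed
plan to stay on track you can do this one small step counts set a phone cue
drink water with it check your stock this week ask for help when you need it
note how you feel keep the streak going be kind to your own pace
# complex-words
medication important remember carefully consistently management
organizer routinely beneficial successfully
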